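---
title: "Hybrid electrophysiology modeling and machine learning for CRT response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid electrophysiology modeling and machine learning for CRT response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtsim)
```

## The modeling problem

Cardiac resynchronization therapy (CRT) paces both ventricles to correct the
dyssynchronous activation of left bundle branch block (LBBB), but 30--50% of
recipients do not improve. `crtsim` implements a hybrid strategy for
predicting response before implantation: simulate each candidate's ventricular
activation twice -- once in the intrinsic LBBB mode and once under
biventricular (BiV) pacing from plausible lead positions -- derive electrical
dyssynchrony biomarkers from the two simulations, and feed them, together with
pre-operative clinical variables, to supervised classifiers evaluated with
in-loop feature selection and cross-validation.

Because no patient data ships with the package, a synthetic-data layer stands
in for the cohort at two fidelities: a fast statistical feature-table
generator, and a full in-silico mode that runs the entire electrophysiology
pipeline per synthetic patient. Everything downstream of data ingestion --
activation solver, ECG forward model, conductivity personalization,
biomarkers, and the classification pipeline -- is the same code a real cohort
would use.

## Idealized biventricular anatomy

`build_ventricles()` constructs a labeled tetrahedral mesh from an implicit
two-ellipsoid geometry: a full truncated-ellipsoid LV shell and a thin-walled
RV crescent attached to its septal side, voxelized on a regular grid (default
edge 4 mm) and split into tetrahedra with a consistent 6-tet decomposition, so
the mesh is conformal and every element has volume $h^3/6$. This is the
desk-scale analogue of a segmented CT anatomy: labels, not millimeter-accurate
shape, are what the downstream mathematics consumes.

Each element carries a wall label (`LV_free`, `septum`, `RV_free`), a
transmural layer (`endo`/`mid`/`epi` by thirds of the normalized depth between
the endocardial and epicardial surfaces), an AHA segment (1--17, LV only;
basal and mid rings in 60° sectors, apical in 90° sectors, apex cap below the
endocardial apex), and a tissue class (`normal`, `fibrosis`, `scar`). The
defaults are a dilated, **spherically remodeled** LV (inner semi-axes
42 x 42 x 52 mm, 12 mm wall; cavity volume about 190 ml): this is the typical
phenotype of the CRT candidate population, and on it the simulated LBBB total
activation times (about 230--260 ms at unit conductivity) and the strong TAT
reduction under BiV pacing match the ranges this class of models reports. The
12 mm wall keeps three element layers across the wall at 4 mm resolution, so
all 51 (segment, layer) region codes are populated.

Lesions are applied at the same granularity as an expert MRI damage
annotation: a `lesion_spec()` maps (AHA segment, layer) cells to `fibrosis` or
`scar`. Scar is non-excitable and excluded from propagation and from the
myocardial tissue volume (MTV); fibrosis conducts at 1% conductivity, i.e.
10% of the local speed.

Two idealizations deserve explicit caveats. First, the base is a flat
truncation plane; a thick fibrosis sheet ending at that plane becomes a
sealed slow pocket that real basal anatomy (valve rings, atria) does not
produce, which is why the in-silico patient generator keeps fibrosis off the
basal ring. Second, voxelization stair-steps the surfaces; volumes converge
at first order (the default mesh is within ~1% of the analytic shell volume,
tested at 5%).

Node and element indices are 1-based throughout, the R convention. Units are
mm, ms, and mm/ms everywhere.

## Anisotropic activation model

Activation times solve a first-arrival (Eikonal) problem: cardiac tissue
conducts anisotropically with a conductivity ratio $\rho = 4$ along vs across
the local fiber direction, and velocity scales as the square root of
conductivity, giving the physiological 2:1 velocity ratio. With a global
dimensionless conductivity scale $g$, the along-fiber speed is
$v_f = v_0\sqrt{g}$ (default $v_0 = 0.6$ mm/ms) and the cross-fiber speed
$v_t = v_f/2$.

A path in direction $d$ at angle $\theta$ to the fiber travels at the ray
speed of the Riemannian metric,

$$ v(d) = \left(\frac{\cos^2\theta}{v_f^2} +
          \frac{\sin^2\theta}{v_t^2}\right)^{-1/2}, $$

whose point response is the elliptical norm $\sqrt{x^\top D^{-1} x}$ with
$D = v_f^2\, ff^\top + v_t^2 (I - ff^\top)$. The distinction from the
front-normal speed $\sqrt{v_f^2\cos^2\theta + v_t^2\sin^2\theta}$ matters for
any path-based solver: the normal-speed form is not convex as a path metric,
so zig-zag paths would cross fibers at $1.155\,v_t$ and the measured planar
front ratio would be 1.73 rather than 2. The package's acceptance target
(planar front speed along:across = 2.0 at a 4:1 conductivity ratio) follows
directly from the ray-speed form.

The solver is multi-source Dijkstra (compiled) on a lattice edge graph.
Because mesh nodes sit on a regular grid, the graph is generated from a
family of primitive integer offsets (the *stencil*); order 1 is the local
neighborhood, higher orders add longer virtual edges that refine the
directional resolution of the graph metric. Every candidate edge is validated
by sampling its segment against the voxel cell set -- edges cannot tunnel
across cavities or scar -- and its travel time is the line integral of the
local inverse speed (harmonic-mean speed), exact in homogeneous tissue.
Numerical accuracy is controlled by two exposed knobs:

* `stencil` (default 2): directional error of the graph metric. Order 2 is
  used for all pipeline work (biomarkers, personalization), where maxima and
  means of activation times are the quantities of interest.
* `stencil_aspect`: per-axis elongation of the stencil. Under a 2:1
  anisotropy the metric stretches angles near the fiber axis, so matching the
  aspect to the anisotropy restores uniform angular resolution. At 2 mm
  resolution with `stencil = 3, stencil_aspect = c(2, 1, 1)` the point
  response of a homogeneous slab matches the elliptical closed form within 3%
  (maximum over nodes beyond the source-local shell); this is the convergent
  configuration the accuracy test runs.

The fiber field is the simplest member of the rule-based family: the helix
angle interpolates linearly from +60° (endocardium) to -60° (epicardium)
across the transmural depth, with fibers tangent to the local wall surface.
Mid-depth fibers are circumferential.

Geodesic distance biomarkers (`geodesic_distance()`) solve the isotropic
unit-speed special case **including scar** by default: they mimic ruler
measurements on CT/MRI images, which do not know about excitability. An
`exclude_scar` flag exists for sensitivity analyses.

The late-activation zone (`late_activation_zone()`) is the set of LV (free
wall + septum) nodes activating in the last decile of the activation span
(`fraction = 0.9`). The threshold is this package's declared convention --
the definition of "late" is not standardized -- and is exposed as a
parameter.

## LBBB and BiV pacing protocols

In LBBB the left conduction system is silent and the ventricles are engaged
through the right bundle. `grow_rv_tree()` builds a deterministic fractal
surrogate of the right His--Purkinje system on the RV endocardial surface: a
trunk of about 40 mm from a basal septal origin to the RV apex, then binary
branching (defaults: 6 generations, 8 mm branches, 20° half-angle -- declared
defaults; only the trunk length and the 3 mm/ms His--Purkinje velocity are
literature-anchored). The tree is insulated from the working myocardium
except at its terminals (PMJs), each of which fires at its tree path length
divided by the conduction velocity; `lbbb_sources()` turns the PMJs into the
Eikonal boundary condition. BiV pacing stimulates the myocardium directly at
two sites -- the RV endocardial apex and an epicardial LV free-wall position
in the coronary-sinus-accessible posterolateral band
(`place_pacing_sites()`) -- with zero inter-lead delay by default.

## ECG forward model and QRS duration

Each activated element contributes an equivalent current dipole
$p(t) = -A'(t - \mathrm{AT})\, \nabla \mathrm{AT}\, V$, where $A$ is a
template action potential (logistic upstroke, $\tau = 0.4$ ms, -85 to +25 mV;
only depolarization matters for the QRS, so no repolarization is modeled) and
$\nabla \mathrm{AT}$ is the linear-tetrahedron gradient of the nodal
activation times. Dipoles are projected to nine electrode positions with the
infinite-homogeneous-medium kernel $p\cdot r / (4\pi |r|^3)$; a torso with
lungs would scale and smooth the potentials but barely move QRS timing, which
is all the pipeline consumes, so the volume-conductor simplification is
declared rather than corrected for. Electrode positions are fixed synthetic
landmarks on a virtual torso (the placement relative to the heart is
otherwise under-determined). Standard lead algebra produces the 12 leads; the
Einthoven and Goldberger identities are exact by construction and asserted to
1e-12 in the tests.

QRS boundaries use an operational 5% amplitude threshold per lead (first and
last sample above 5% of that lead's peak |amplitude|, `dt = 0.5` ms): "Q peak
to S peak" is not an operational definition, so the threshold rule is this
package's convention. The reported QRSd is the maximum per-lead duration; the
mean per-lead duration is also returned and drives personalization.

## Conductivity personalization

`fit_conductivity()` fits the single global scale $g$ so the simulated *mean*
per-lead QRS duration matches a target value, per patient and per pacing mode
independently (PMJ onsets stay fixed; the Purkinje velocity is never fitted).
Because all speeds scale as $\sqrt{g}$, the simulated QRSd is monotonically
non-increasing in $g$; the fit brackets the target on a log-spaced grid
(bounds default to $g \in [0.1, 10]$) and then root-finds on $\log g$.
Unreachable targets return the boundary solution with a non-convergence flag.
Self-consistency is tested as parameter recovery: over 20 synthetic patients
with $g^\ast$ log-uniform in [0.25, 4], the median relative error is required
below 2% and the maximum below 5%. The residual error is dominated by the
0.5 ms sampling quantization of the QRS boundaries.

## Biomarkers

Per pacing mode: total activation time (TAT = max - min finite activation
time); QRSd; the interventricular dyssynchrony index AT_RVLV (latest LV
activation minus latest RV free-wall activation -- "LV" here means free wall
plus septum, since the septum activates with the LV in LBBB physiology; the
chamber convention is declared because it is genuinely ambiguous);
the normalized intraventricular index mAT_STLV ((mean LV-free-wall AT - mean
septal AT)/TAT, volume-weighted nodal means with an unweighted mode for
sensitivity checks); and IntAV_STLV, the integral over the activation window
of the absolute difference between the septal and LV-free-wall
activated-volume fractions (1 ms grid, trapezoidal quadrature; halving the
step moves smooth-map values by under 1%).

Geometry features: MTV (excitable myocardium, scar excluded), InfarctV
(scar + fibrosis), their ratio, and ruler-like distances from the LV pacing
site to the RV site (DLvRv), the lesion border (DLvInfarct), and the LAT zone
(DLvLATZ). Undefined features (no lesion, zero baseline) are NA markers,
never zeros, so the missing-value exclusion rule of the ML stage is exercised
honestly.

Changes under BiV against the LBBB baseline are relative percentages,
$\Delta X = 100\,(X_{BiV} - X_{LBBB})/X_{LBBB}$, except mAT_STLV, which is
already normalized and reported as an absolute increment.

## Classification pipeline

`cohort_table()` couples the feature matrix with per-column metadata (kind,
provenance, pre-operative safety) and the post-operative outcomes. Response
criteria: EF5/EF10/EF15 on the absolute percentage-point EF increase, ESV15
on a >15% end-systolic volume reduction, and their EF10∧ESV15 conjunction.

Preprocessing restricts to pre-op-safe columns, drops any column containing a
missing value (column-wise, no imputation), drops zero-variance columns, and
removes collinear features above |r| = 0.85. Which member of a correlated
pair is dropped is not standardized, so columns carry a declared priority --
clinical before model-derived provenances, alphabetical within -- and the
lower-priority column goes; the surviving set has no pair above the
threshold (asserted against a full pairwise scan).

Feature selection runs *inside* the cross-validation loop on training rows
only, as do scaling and classifier fitting; an audit log records exactly
which rows each fit saw, and a test asserts no test-fold row ever reaches a
scaler, selector, or classifier. Three selectors return the top 8 features:
univariate statistical testing (two-sample t-test for continuous, chi-squared
for categorical columns -- uncorrected, since the p-values are used as ranks,
not inferences), random-forest permutation importance, and L1-penalized
logistic coefficients (fixed penalty 0.05 with a small internal relaxation
grid if everything shrinks to zero; no value is standard). Classifiers:
logistic regression, LDA, linear-kernel SVM (decision values squashed through
a logistic into score units), and random forest. No hyperparameter search
anywhere, deliberately: simple models with fixed settings on a small cohort.

Evaluation is either Leave-One-Out (all out-of-fold scores pooled into one
ROC curve, a single AUC) or repeated stratified 5-fold CV (AUC per fold,
mean ± SD over folds x repeats; the default 1000 repeats is scaled down in
the test suite, which uses 1--2 repeats -- the estimator is the same).
Binary metrics are reported at the Youden-J-optimal cutoff of the pooled
scores, a declared rule (reported cutoffs in this literature are data-derived
without a stated criterion). `pca_lr()` fits PCA inside the CV loop and runs
logistic regression on 2--10 component scores; at full rank it reproduces the
plain logistic fit exactly (rotation invariance), which is asserted to 1e-9.
`kmeans_clusters()` clusters the first two PC scores (best of 10 restarts)
and reports per-cluster outcomes -- the unsupervised counterpart.

## What the synthetic cohort does and does not emulate

`default_cohort_spec()` encodes group-conditional marginals (mean ± SD or
event probabilities) for responders vs nonresponders under the EF10
criterion, for three feature families: pre-operative clinical variables
(e.g. EF 23 ± 5 vs 29 ± 6%, BMI 27 ± 5 vs 30 ± 5), CT/MRI-derived geometry
(e.g. lesion distance DLvInfarct 45 ± 28 vs 28 ± 27 mm), and simulated
LBBB/BiV indices (e.g. TAT 269 ± 109 -> 141 ± 31 ms in responders). The echo
mechanical-dyssynchrony block is available for only 34/57 of patients and is
drawn jointly missing, exercising the missing-column rule. Outcomes come
from the group-conditional outcome model with the EF change truncated at the
EF10 cutoff, so latent labels and outcome-derived labels agree by
construction. Two derived variants support property tests:
`null_cohort_spec()` (identical group distributions -- classifiers must sit
at AUC 0.5) and `model_effects_cohort_spec()` (clinical features nulled,
model-derived effects kept -- hybrid classifiers must beat clinical-only
ones).

Features are independent within group except for the deterministically
derived TAT/MTV columns; the real covariance structure of such cohorts is
unknown, and no attempt is made to invent one. Consequently, passing tests
demonstrate that the pipeline machinery is correct and that it detects
planted group structure at realistic effect sizes -- they do not validate
patient-level predictive accuracy, which would require real data.

The in-silico mode (`generate_insilico_patients()`) replaces the drawn model
features with actually simulated ones: per patient, an anatomy scale jitter
(0.9--1.12), an optional lesion map (ischemic scar cores with intramural
fibrosis borders, or non-ischemic mid/apical intramural septal fibrosis; 70%
prevalence), a per-patient conductivity (log-uniform in [0.5, 2]), pacing
sites jittered within the posterolateral band, and the full LBBB + BiV
pipeline. On these defaults every patient's TAT falls under BiV pacing and
the mean relative change is below -20%, the qualitative resynchronization
signature; the magnitude is smaller than real cohorts report (about -45%),
mainly because one shared conductivity serves both modes here whereas
clinical personalization fits each mode to its own measured QRSd.

## Problem sizes and runtime choices

Default meshes have ~5,000 nodes / ~19,000 tetrahedra (4 mm edges).
The test suite uses: 10 in-silico patients at default resolution for the
resynchronization property; 20 personalization recoveries; 200 seeds for the
permutation-null AUC; 50 replicates of n = 200 cohorts for the
hybrid-vs-clinical ordering; and the 2 mm slab (~35,000 nodes) only for the
closed-form convergence check. These sizes were chosen so the full suite
completes in a few minutes while keeping every statistical assertion
comfortably powered.

## Known limitations

* Anatomy is idealized; no valves, atria, papillary muscles, or
  patient-specific shape. The flat base truncation is the largest geometric
  artifact (see above).
* The volume conductor is an infinite homogeneous medium; torso and lung
  inhomogeneities, and hence absolute ECG amplitudes, are out of scope.
  Normalized morphology and timing are the supported outputs.
* Only depolarization is modeled: no T waves, no repolarization gradients.
* The Purkinje surrogate is right-sided and one-way coupled; His-bundle or
  fusion pacing cannot be represented.
* Graph first-arrival solvers have direction-dependent discretization error;
  the stencil controls it and the convergent configuration is documented, but
  very thin structures (the 5 mm RV free wall at 4 mm voxels) are resolved by
  a single element layer and conduct at their mid-wall fiber angle.
* Synthetic cohorts reproduce marginal group statistics, not joint
  distributions; headline patient-level accuracies from real cohorts are not
  reproduction targets.
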