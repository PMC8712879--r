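Package: crtsim
Title: Hybrid Cardiac Electrophysiology Modeling and Machine Learning for
    CRT Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates ventricular electrical activation on idealized
    biventricular anatomies with an anisotropic Eikonal front model, derives
    12-lead body-surface QRS complexes through an equivalent-dipole forward
    model, personalizes a global myocardial conductivity against a target QRS
    duration, and computes electrical dyssynchrony biomarkers for intrinsic
    left-bundle-branch-block activation and biventricular pacing. The
    model-derived features are combined with synthetic clinical feature tables
    into hybrid cohorts on which cross-validated machine-learning classifiers
    of cardiac resynchronization therapy (CRT) response are trained and
    evaluated, with feature selection performed inside the cross-validation
    loop.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    MASS,
    e1071,
    randomForest,
    glmnet,
    pROC
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
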