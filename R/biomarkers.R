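# Model-derived biomarkers of ventricular activation and geometry.
#
# Activation indices (TAT, AT_RVLV, mAT_STLV, IntAV_STLV), ECG-derived QRSd,
# geometry/lesion features (MTV, InfarctV, pacing-site distances) and the
# relative-change (delta) features of BiV pacing against the LBBB baseline.
# Conventions: "LV" for chamber maxima/means = LV free wall + septum (the
# septum activates with the LV in LBBB physiology); node means are
# volume-weighted with lumped nodal volumes; undefined features are NA
# markers, never zeros.

# lumped nodal volumes (non-scar elements), mm^3
.node_volumes <- function(mesh) {
  n <- nrow(mesh$nodes)
  keep <- mesh$tissue_class != "scar"
  idx <- as.vector(mesh$tets[keep, , drop = FALSE])
  w <- rep(mesh$elem_volume[keep] / 4, 4)
  vapply(split(w, factor(idx, levels = seq_len(n))), sum, 0)
}

#' Interventricular dyssynchrony AT_RVLV, ms
#'
#' Difference between the latest activation of the LV (free wall + septum)
#' and of the RV free wall; positive when the LV finishes later.
#'
#' @param map an `activation_map`
#' @param mesh the mesh it was computed on
#' @return ms
#' @export
at_rvlv <- function(map, mesh) {
  at <- map$at
  lv <- mesh$node_wall %in% c("LV_free", "septum") & is.finite(at)
  rv <- mesh$node_wall == "RV_free" & is.finite(at)
  if (!any(lv) || !any(rv)) stop("a chamber has no finite activation times")
  max(at[lv]) - max(at[rv])
}

#' Intraventricular dyssynchrony mAT_STLV (dimensionless)
#'
#' (mean activation time of the LV free wall - mean activation time of the
#' septum) / TAT, with volume-weighted nodal means.  NA when TAT is 0.
#'
#' @param map an `activation_map`
#' @param mesh the mesh
#' @param weighted volume-weight the node means (default); unweighted mode
#'   for sensitivity checks
#' @return dimensionless, or NA if undefined
#' @export
mat_stlv <- function(map, mesh, weighted = TRUE) {
  at <- map$at
  total <- tat(map)
  if (total <= 0) return(NA_real_)
  w <- if (weighted) .node_volumes(mesh) else rep(1, length(at))
  sel_lv <- mesh$node_wall == "LV_free" & is.finite(at) & w > 0
  sel_st <- mesh$node_wall == "septum" & is.finite(at) & w > 0
  if (!any(sel_lv) || !any(sel_st)) stop("LV free wall or septum has no finite activation")
  wm <- function(s) sum(at[s] * w[s]) / sum(w[s])
  (wm(sel_lv) - wm(sel_st)) / total
}

#' Activated-volume curves of septum and LV free wall
#'
#' `AV_X(t)` is the myocardial volume (mm^3) of region X activated by time t
#' (element activation time = mean of its nodal times); scar is excluded
#' from both the running volumes and the totals.
#'
#' @param map an `activation_map`
#' @param mesh the mesh
#' @param dt time grid step, ms
#' @return list with `time`, `av_st`, `av_lat` (mm^3), totals `v_st`, `v_lat`
#' @export
activation_volume_curves <- function(map, mesh, dt = 1) {
  at <- map$at
  fin4 <- is.finite(at[mesh$tets[, 1]]) & is.finite(at[mesh$tets[, 2]]) &
    is.finite(at[mesh$tets[, 3]]) & is.finite(at[mesh$tets[, 4]])
  at_el <- (at[mesh$tets[, 1]] + at[mesh$tets[, 2]] +
            at[mesh$tets[, 3]] + at[mesh$tets[, 4]]) / 4
  ok <- mesh$tissue_class != "scar" & fin4
  st <- ok & mesh$wall_label == "septum"
  lat <- ok & mesh$wall_label == "LV_free"
  fin <- at[is.finite(at)]
  tgrid <- seq(min(fin), max(fin) + dt, by = dt)
  cum_vol <- function(sel) {
    if (!any(sel)) return(rep(0, length(tgrid)))
    vapply(tgrid, function(t) sum(mesh$elem_volume[sel & at_el <= t]), 0)
  }
  list(time = tgrid, av_st = cum_vol(st), av_lat = cum_vol(lat),
       v_st = sum(mesh$elem_volume[st]), v_lat = sum(mesh$elem_volume[lat]))
}

# trapezoidal integral of |f1 - f2| over t
.abs_diff_integral <- function(t, f1, f2) {
  y <- abs(f1 - f2)
  sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
}

#' Integral index of LV activation dyssynchrony IntAV_STLV, ms
#'
#' Integral over the activation window of the absolute difference between
#' the septal and LV-free-wall activated volume fractions.
#'
#' @inheritParams activation_volume_curves
#' @return ms
#' @export
intav_stlv <- function(map, mesh, dt = 1) {
  cv <- activation_volume_curves(map, mesh, dt)
  if (cv$v_st <= 0 || cv$v_lat <= 0) stop("septum or LV free wall has no active volume")
  .abs_diff_integral(cv$time, cv$av_st / cv$v_st, cv$av_lat / cv$v_lat)
}

#' Geometry and lesion features
#'
#' MTV is the myocardial tissue volume of the excitable myocardium (scar
#' excluded); InfarctV the damaged (scar + fibrosis) volume.  Distances are
#' ruler-like isotropic geodesics from the LV pacing site: to the RV pacing
#' site (DLvRv), to the lesion border (DLvInfarct, NA when there is no
#' lesion), and to the late-activation zone (DLvLATZ).
#'
#' @param mesh a `ventricular_mesh` (lesions applied)
#' @param pacing a [place_pacing_sites()] config
#' @param lat_zone node set from [late_activation_zone()] (or NULL to skip)
#' @param stencil stencil order for the distance solves
#' @return list MTV (ml), InfarctV (ml), InfarctV_MTV, DLvRv, DLvInfarct,
#'   DLvLATZ (mm)
#' @export
geometry_features <- function(mesh, pacing, lat_zone = NULL, stencil = 2L) {
  vol <- mesh$elem_volume
  mtv <- sum(vol[mesh$tissue_class != "scar"]) / 1000
  infarct <- sum(vol[mesh$tissue_class %in% c("scar", "fibrosis")]) / 1000
  lesion_nodes <- unique(as.vector(
    mesh$tets[mesh$tissue_class %in% c("scar", "fibrosis"), , drop = FALSE]))
  d_rv <- geodesic_distance(mesh, pacing$lv_site, pacing$rv_site, stencil = stencil)
  d_inf <- if (length(lesion_nodes))
    geodesic_distance(mesh, pacing$lv_site, lesion_nodes, stencil = stencil)
  else NA_real_
  d_lat <- if (!is.null(lat_zone) && length(lat_zone))
    geodesic_distance(mesh, pacing$lv_site, lat_zone, stencil = stencil)
  else NA_real_
  list(MTV = mtv, InfarctV = infarct, InfarctV_MTV = infarct / mtv,
       DLvRv = d_rv, DLvInfarct = d_inf, DLvLATZ = d_lat)
}

#' All activation/ECG biomarkers for one pacing mode
#'
#' @param mesh the mesh
#' @param map the `activation_map` of the mode
#' @param qrs the [measure_qrs()] result of the simulated ECG (or NULL to
#'   skip ECG indices)
#' @param dt grid step for the activated-volume curves, ms
#' @return a `biomarker_set` list: TAT, QRSd, QRSd_mean, AT_RVLV, mAT_STLV,
#'   IntAV_STLV, TAT_MTV (ms/ml)
#' @export
compute_biomarkers <- function(mesh, map, qrs = NULL, dt = 1) {
  mtv <- sum(mesh$elem_volume[mesh$tissue_class != "scar"]) / 1000
  structure(list(
    TAT = tat(map),
    QRSd = if (is.null(qrs)) NA_real_ else qrs$qrsd,
    QRSd_mean = if (is.null(qrs)) NA_real_ else qrs$mean_duration,
    AT_RVLV = at_rvlv(map, mesh),
    mAT_STLV = mat_stlv(map, mesh),
    IntAV_STLV = intav_stlv(map, mesh, dt = dt),
    TAT_MTV = tat(map) / mtv
  ), class = "biomarker_set")
}

#' Relative change of biomarkers under BiV pacing vs the LBBB baseline
#'
#' For every shared feature, Delta = 100 (X_BiV - X_LBBB) / X_LBBB (percent),
#' except mAT_STLV, which is already a normalized quantity and is reported
#' as the absolute increment X_BiV - X_LBBB.  A relative delta with a zero
#' baseline is NA.
#'
#' @param lbbb,biv `biomarker_set`s (or named lists) of the two modes
#' @return named list of delta features (names prefixed `d`)
#' @export
delta_features <- function(lbbb, biv) {
  keys <- intersect(names(lbbb), names(biv))
  out <- lapply(keys, function(k) {
    a <- lbbb[[k]]; b <- biv[[k]]
    if (is.na(a) || is.na(b)) return(NA_real_)
    if (k == "mAT_STLV") return(b - a)
    if (a == 0) return(NA_real_)
    100 * (b - a) / a
  })
  names(out) <- paste0("d", keys)
  out
}
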