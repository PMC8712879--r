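# Forward 12-lead ECG from an activation map.
#
# Each activated element contributes an equivalent current dipole
# p(t) = -A'(t - AT) * grad(AT) * volume, where A is a template action
# potential (only the depolarization upstroke matters for the QRS).  The
# dipoles are projected to the torso electrodes with the
# infinite-homogeneous-medium kernel p.(r - x) / (4 pi |r - x|^3); standard
# limb/augmented/precordial lead algebra then yields the 12-lead QRS.

#' Template action potential (depolarization upstroke only)
#'
#' Logistic upstroke from the resting to the plateau potential; the QRS is
#' generated by the spatial gradient of depolarization times, so no
#' repolarization phase is modeled.
#'
#' @param rest resting potential, mV
#' @param peak plateau potential, mV
#' @param tau upstroke time constant, ms
#' @return an `ap_template` list with `value(s)` and `slope(s)` functions of
#'   local time `s = t - AT`
#' @export
ap_template <- function(rest = -85, peak = 25, tau = 0.4) {
  stopifnot(tau > 0, peak > rest)
  amp <- peak - rest
  structure(list(
    rest = rest, peak = peak, tau = tau, amp = amp,
    value = function(s) rest + amp / (1 + exp(-s / tau)),
    slope = function(s) {
      z <- exp(-abs(s) / tau)              # symmetric, overflow-safe
      amp / tau * z / (1 + z)^2
    }
  ), class = "ap_template")
}

# per-element gradient of the nodal activation-time field (linear tets)
.elem_grad_at <- function(mesh, at) {
  t1 <- mesh$tets[, 1]; t2 <- mesh$tets[, 2]; t3 <- mesh$tets[, 3]; t4 <- mesh$tets[, 4]
  p0 <- mesh$nodes[t1, , drop = FALSE]
  e1 <- mesh$nodes[t2, , drop = FALSE] - p0
  e2 <- mesh$nodes[t3, , drop = FALSE] - p0
  e3 <- mesh$nodes[t4, , drop = FALSE] - p0
  b1 <- at[t2] - at[t1]; b2 <- at[t3] - at[t1]; b3 <- at[t4] - at[t1]
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  c23 <- cr(e2, e3); c31 <- cr(e3, e1); c12 <- cr(e1, e2)
  det <- rowSums(e1 * c23)
  grad <- (c23 * b1 + c31 * b2 + c12 * b3) / det
  list(grad = grad, det = det)
}

#' Electrode surface potentials from an activation map
#'
#' @param map an `activation_map`
#' @param mesh the mesh it was computed on
#' @param torso a [torso_electrodes()] model
#' @param ap an [ap_template()]
#' @param dt sampling step, ms (default 0.5)
#' @return list with `time` (ms) and `potentials`, a (time x 9) matrix in
#'   arbitrary linear units with columns RA, LA, LL, V1..V6; the number of
#'   elements skipped for undefined gradients is in `skipped`
#' @export
surface_potentials <- function(map, mesh, torso, ap = ap_template(), dt = 0.5) {
  at <- map$at
  el <- torso$electrodes
  # electrodes must lie outside the myocardium
  for (e in seq_len(nrow(el))) {
    d2 <- min(colSums((t(mesh$nodes) - el[e, ])^2))
    if (sqrt(d2) < mesh$h) stop("electrode lies inside the myocardium")
  }
  active <- mesh$tissue_class != "scar"
  finite4 <- is.finite(at[mesh$tets[, 1]]) & is.finite(at[mesh$tets[, 2]]) &
    is.finite(at[mesh$tets[, 3]]) & is.finite(at[mesh$tets[, 4]])
  use <- active & finite4
  if (!any(use)) stop("no activated elements")
  ga <- .elem_grad_at(mesh, at)
  degen <- use & (!is.finite(ga$det) | abs(ga$det) < 1e-12)
  skipped <- sum(degen)
  use <- use & !degen

  grad <- ga$grad[use, , drop = FALSE]
  vol <- mesh$elem_volume[use]
  ctr <- mesh$elem_center[use, , drop = FALSE]
  at_el <- (at[mesh$tets[use, 1]] + at[mesh$tets[use, 2]] +
            at[mesh$tets[use, 3]] + at[mesh$tets[use, 4]]) / 4
  moment <- -grad * vol                           # dipole moment per unit A'

  W <- matrix(0, nrow(ctr), nrow(el))
  for (e in seq_len(nrow(el))) {
    r <- matrix(el[e, ], nrow(ctr), 3, byrow = TRUE) - ctr
    r3 <- rowSums(r^2)^1.5
    W[, e] <- rowSums(moment * r) / (4 * pi * r3)
  }

  fin <- at[is.finite(at)]
  tgrid <- seq(floor(min(fin) - 5), ceiling(max(fin) + 10), by = dt)
  nt <- length(tgrid)
  pot <- matrix(0, nt, nrow(el), dimnames = list(NULL, rownames(el)))
  chunk <- max(1L, floor(4e6 / length(at_el)))
  i <- 1L
  while (i <= nt) {
    j <- min(i + chunk - 1L, nt)
    S <- outer(tgrid[i:j], at_el, function(t, a) ap$slope(t - a))
    pot[i:j, ] <- S %*% W
    i <- j + 1L
  }
  list(time = tgrid, potentials = pot, skipped = skipped)
}

#' Derive the 12 standard leads from electrode potentials
#'
#' Wilson central terminal = mean(RA, LA, LL); Einthoven limb leads,
#' Goldberger augmented leads, and precordial leads V1..V6 referenced to the
#' central terminal.
#'
#' @param pot list with `time` and a 9-column `potentials` matrix
#'   (RA, LA, LL, V1..V6), as returned by [surface_potentials()]
#' @return an `ecg12`: list with `time`, `dt` and a (time x 12) `leads`
#'   matrix (I, II, III, aVR, aVL, aVF, V1..V6)
#' @export
derive_leads <- function(pot) {
  p <- pot$potentials
  need <- c("RA", "LA", "LL", paste0("V", 1:6))
  if (!all(need %in% colnames(p))) stop("all 9 electrode series are required")
  if (length(pot$time) != nrow(p)) stop("time/potential length mismatch")
  RA <- p[, "RA"]; LA <- p[, "LA"]; LL <- p[, "LL"]
  wct <- (RA + LA + LL) / 3
  leads <- cbind(I = LA - RA, II = LL - RA, III = LL - LA,
                 aVR = RA - (LA + LL) / 2, aVL = LA - (RA + LL) / 2,
                 aVF = LL - (RA + LA) / 2,
                 p[, paste0("V", 1:6)] - wct)
  colnames(leads) <- c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6))
  structure(list(time = pot$time, dt = diff(pot$time[1:2]), leads = leads),
            class = "ecg12")
}

#' Normalize each lead to unit peak amplitude
#' @param ecg an `ecg12`
#' @return the `ecg12` with every nonzero lead scaled to max |amplitude| 1
#' @export
normalize_leads <- function(ecg) {
  mx <- apply(abs(ecg$leads), 2, max)
  mx[mx == 0] <- 1
  ecg$leads <- sweep(ecg$leads, 2, mx, "/")
  ecg$normalized <- TRUE
  ecg
}

#' Measure QRS boundaries and duration
#'
#' Per lead, onset `T_Q` is the first and offset `T_S` the last sample whose
#' absolute amplitude exceeds `threshold_frac` of that lead's peak absolute
#' amplitude.  The reported QRS duration (QRSd) is the maximum per-lead
#' duration across the 12 leads; the mean per-lead duration (used as the
#' personalization target) is also returned.
#'
#' @param ecg an `ecg12`
#' @param threshold_frac amplitude threshold fraction (default 0.05)
#' @return a `qrs_measurement`: data frame `per_lead` (lead, t_q, t_s,
#'   duration) plus `qrsd` (max) and `mean_duration`
#' @export
measure_qrs <- function(ecg, threshold_frac = 0.05) {
  leads <- ecg$leads
  nl <- ncol(leads)
  t_q <- t_s <- dur <- numeric(nl)
  zero <- logical(nl)
  for (k in seq_len(nl)) {
    a <- abs(leads[, k])
    m <- max(a)
    if (m == 0) { zero[k] <- TRUE; next }
    idx <- which(a > threshold_frac * m)
    t_q[k] <- ecg$time[idx[1]]
    t_s[k] <- ecg$time[idx[length(idx)]]
    dur[k] <- t_s[k] - t_q[k]
  }
  if (all(zero)) stop("all leads are zero")
  if (any(zero))
    warning(sprintf("%d all-zero lead(s) excluded from the mean duration", sum(zero)))
  per_lead <- data.frame(lead = colnames(leads), t_q = t_q, t_s = t_s,
                         duration = dur, stringsAsFactors = FALSE)
  structure(list(per_lead = per_lead, qrsd = max(dur),
                 mean_duration = mean(dur[!zero])),
            class = "qrs_measurement")
}

#' Simulate a 12-lead QRS from an activation map
#'
#' Convenience wrapper: [surface_potentials()] then [derive_leads()].
#'
#' @inheritParams surface_potentials
#' @return an `ecg12`
#' @export
simulate_ecg <- function(map, mesh, torso, ap = ap_template(), dt = 0.5) {
  derive_leads(surface_potentials(map, mesh, torso, ap, dt))
}

#' @export
print.qrs_measurement <- function(x, ...) {
  cat(sprintf("QRS: max duration %.1f ms, mean over leads %.1f ms\n",
              x$qrsd, x$mean_duration))
  invisible(x)
}
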