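# Personalization of the global conductivity scale.
#
# One dimensionless conductivity scale g multiplies the reference
# conductivity of the whole myocardium (fibrosis stays at its fixed fraction
# of the local value, scar stays excluded).  g is fitted so that the mean
# per-lead simulated QRS duration matches a target ("clinical") mean QRSd.
# Because all speeds scale with sqrt(g), the simulated QRSd is monotonically
# non-increasing in g, which makes bracketing + root finding robust; the
# LBBB and BiV protocols are fitted independently (PMJ onsets are fixed, the
# Purkinje velocity is not a fitted parameter).

#' Fit the global conductivity to a target mean QRS duration
#'
#' @param mesh a `ventricular_mesh` with fibers (lesions already applied)
#' @param sources pacing boundary condition: data frame `node`, `onset`
#'   ([lbbb_sources()] for LBBB, the two pacing sites for BiV)
#' @param torso a [torso_electrodes()] model
#' @param target_mean_qrsd target mean per-lead QRS duration, ms
#' @param bounds search interval for g (default `c(0.1, 10)`)
#' @param tol convergence tolerance on the QRSd mismatch, ms
#' @param base_model conduction model supplying `v0`, `rho` and the fibrosis
#'   fraction; its `g` is ignored
#' @param stencil,dt,ap forwarded to the solver and the ECG forward model
#' @param mode tag stored in the result (`"LBBB"` or `"BiV"`)
#' @return a `personalization_result`: `g`, implied `v_f` (mm/ms),
#'   `objective` (|mean QRSd - target| at the optimum, ms), `iterations`,
#'   `converged`, `mode`
#' @export
fit_conductivity <- function(mesh, sources, torso, target_mean_qrsd,
                             bounds = c(0.1, 10), tol = 1,
                             base_model = conduction_model(),
                             stencil = 2L, dt = 0.5, ap = ap_template(),
                             mode = "custom") {
  stopifnot(target_mean_qrsd > 0, length(bounds) == 2, bounds[1] > 0,
            bounds[2] > bounds[1])
  n_eval <- 0L
  qrsd_at <- function(g) {
    n_eval <<- n_eval + 1L
    model <- conduction_model(g = g, v0 = base_model$v0, rho = base_model$rho,
                              fibrosis_fraction = base_model$fibrosis_fraction)
    map <- solve_activation(mesh, model, sources, stencil = stencil)
    ecg <- simulate_ecg(map, mesh, torso, ap = ap, dt = dt)
    measure_qrs(ecg)$mean_duration
  }
  q_lo <- qrsd_at(bounds[1])     # slowest conduction -> longest QRS
  q_hi <- qrsd_at(bounds[2])
  done <- function(g, q, conv) {
    structure(list(g = g, v_f = base_model$v0 * sqrt(g),
                   objective = abs(q - target_mean_qrsd),
                   iterations = n_eval, converged = conv, mode = mode),
              class = "personalization_result")
  }
  if (target_mean_qrsd >= q_lo)
    return(done(bounds[1], q_lo, abs(q_lo - target_mean_qrsd) <= tol))
  if (target_mean_qrsd <= q_hi)
    return(done(bounds[2], q_hi, abs(q_hi - target_mean_qrsd) <= tol))
  # bracket on a log grid, then root-find on log10(g)
  grid <- 10^seq(log10(bounds[1]), log10(bounds[2]), length.out = 7)
  qs <- c(q_lo, vapply(grid[2:6], qrsd_at, 0), q_hi)
  ix <- which(qs[-length(qs)] >= target_mean_qrsd & qs[-1] <= target_mean_qrsd)[1]
  if (is.na(ix)) ix <- which.min(abs(qs - target_mean_qrsd))  # non-monotone samples
  lo <- grid[max(ix - 0, 1)]; hi <- grid[min(ix + 1, 7)]
  f <- function(lg) qrsd_at(10^lg) - target_mean_qrsd
  flo <- qs[ix] - target_mean_qrsd; fhi <- qs[min(ix + 1, 7)] - target_mean_qrsd
  if (flo * fhi > 0) {
    best <- grid[which.min(abs(qs - target_mean_qrsd))]
    return(done(best, qs[which.min(abs(qs - target_mean_qrsd))], FALSE))
  }
  root <- stats::uniroot(f, lower = log10(lo), upper = log10(hi),
                         f.lower = flo, f.upper = fhi, tol = 5e-4)
  g_fit <- 10^root$root
  q_fit <- root$f.root + target_mean_qrsd
  done(g_fit, q_fit, abs(q_fit - target_mean_qrsd) <= tol)
}

#' @export
print.personalization_result <- function(x, ...) {
  cat(sprintf("personalization [%s]: g = %.4f (v_f = %.3f mm/ms), |mean QRSd - target| = %.2f ms, %d evaluations%s\n",
              x$mode, x$g, x$v_f, x$objective, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}
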