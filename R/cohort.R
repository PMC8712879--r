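# Synthetic cohort generation.
#
# The study cohort (57 CRT recipients, 40% EF10 responders) is not publicly
# deposited, so two synthetic stand-ins make the downstream pipeline
# testable: a fast statistical feature-table generator whose per-group
# means/SDs reproduce the published responder vs nonresponder summary
# statistics, and a full in-silico mode that runs the whole EP pipeline
# (anatomy -> LBBB/BiV activation -> ECG -> biomarkers) per synthetic
# patient.  Features are independent within group unless explicitly stated;
# the real cohort's covariance is unknown.

#' Default cohort specification (published group-conditional statistics)
#'
#' Per-feature responder/nonresponder means and SDs (continuous) or event
#' probabilities (categorical) for the clinical, CT/MRI-derived and
#' simulated feature families, with the echo mechanical-dyssynchrony block
#' available only for a subset of patients (34/57), which exercises the
#' missing-value exclusion rule downstream.
#'
#' @return a `cohort_spec` data frame
#' @export
default_cohort_spec <- function() {
  f <- function(name, kind, prov, m1, s1, m0, s0, miss = FALSE)
    data.frame(name = name, kind = kind, provenance = prov, preop_safe = TRUE,
               m_resp = m1, s_resp = s1, m_non = m0, s_non = s0,
               echo_block = miss, stringsAsFactors = FALSE)
  spec <- rbind(
    f("Age",            "continuous", "clinical", 64, 6, 63, 7),
    f("BMI",            "continuous", "clinical", 27, 5, 30, 5),
    f("Male",           "categorical", "clinical", 15 / 23, NA, 23 / 34, NA),
    f("IHD",            "categorical", "clinical", 14 / 23, NA, 22 / 34, NA),
    f("AF",             "categorical", "clinical", 4 / 23, NA, 8 / 34, NA),
    f("NYHA_III",       "categorical", "clinical", 11 / 23, NA, 22 / 34, NA),
    f("QRSd_LBBB",      "continuous", "clinical", 192, 20, 190, 26),
    f("EDV",            "continuous", "clinical", 301, 69, 290, 106),
    f("ESV",            "continuous", "clinical", 231, 59, 207, 87),
    f("EDD",            "continuous", "clinical", 74, 8, 73, 7),
    f("ESD",            "continuous", "clinical", 64, 9, 62, 9),
    f("EF_LBBB",        "continuous", "clinical", 23, 5, 29, 6),
    f("IVD",            "continuous", "clinical", 76, 17, 63, 19, miss = TRUE),
    f("dTs",            "continuous", "clinical", 82, 35, 87, 44, miss = TRUE),
    f("SD12",           "continuous", "clinical", 31, 14, 33, 16, miss = TRUE),
    f("MTV",            "continuous", "ctmri_model", 332, 142, 377, 143),
    f("InfarctV",       "continuous", "ctmri_model", 45, 39, 54, 39),
    f("InfarctV_MTV",   "continuous", "ctmri_model", 0.14, 0.08, 0.16, 0.13),
    f("DLvRv",          "continuous", "ctmri_model", 108, 23, 105, 25),
    f("DLvLATZ",        "continuous", "ctmri_model", 44, 16, 58, 27),
    f("DLvInfarct",     "continuous", "ctmri_model", 45, 28, 28, 27),
    f("TAT_LBBB",       "continuous", "sim_lbbb", 269, 109, 246, 130),
    f("QRSd_sim_LBBB",  "continuous", "sim_lbbb", 192, 21, 187, 24),
    f("AT_RVLV_LBBB",   "continuous", "sim_lbbb", 103, 65, 95, 79),
    f("IntAV_STLV_LBBB", "continuous", "sim_lbbb", 101, 57, 106, 59),
    f("mAT_STLV_LBBB",  "continuous", "sim_lbbb", 0.36, 0.10, 0.36, 0.09),
    f("TAT_BiV",        "continuous", "sim_biv", 141, 31, 138, 46),
    f("QRSd_sim_BiV",   "continuous", "sim_biv", 143, 14, 152, 28),
    f("AT_RVLV_BiV",    "continuous", "sim_biv", 26, 26, 20, 21),
    f("IntAV_STLV_BiV", "continuous", "sim_biv", 34, 15, 33, 16),
    f("mAT_STLV_BiV",   "continuous", "sim_biv", 0.29, 0.14, 0.27, 0.13),
    f("dTAT",           "continuous", "sim_delta", -45, 18, -45, 24),
    f("dQRSd_sim",      "continuous", "sim_delta", -30, 12, -22, 20),
    f("dAT_RVLV",       "continuous", "sim_delta", -75, 21, -76, 27),
    f("dIntAV_STLV",    "continuous", "sim_delta", -51, 36, -53, 52),
    f("dmAT_STLV",      "continuous", "sim_delta", -0.07, 0.18, -0.09, 0.15)
  )
  # group-conditional outcome model (EF change truncated to agree with the
  # EF10 label; ESV change free)
  attr(spec, "outcomes") <- list(
    delta_ef = list(m_resp = 17, s_resp = 5, m_non = 3, s_non = 5, truncate_at = 10),
    delta_esv = list(m_resp = -47, s_resp = 19, m_non = -9, s_non = 37))
  attr(spec, "echo_avail") <- 34 / 57
  class(spec) <- c("cohort_spec", class(spec))
  spec
}

#' Cohort specification with no group effects (permutation null)
#'
#' Every feature keeps its pooled marginal distribution but responders and
#' nonresponders are identically distributed: any classifier should be at
#' chance (AUC 0.5) on cohorts drawn from this specification.
#'
#' @return a `cohort_spec`
#' @export
null_cohort_spec <- function() {
  spec <- default_cohort_spec()
  m <- (spec$m_resp + spec$m_non) / 2
  s <- ifelse(spec$kind == "continuous", sqrt((spec$s_resp^2 + spec$s_non^2) / 2), NA)
  spec$m_resp <- spec$m_non <- m
  spec$s_resp <- spec$s_non <- s
  spec
}

#' Cohort specification with effects planted on model-derived features only
#'
#' Clinical features are nulled to their pooled distributions while the
#' CT/MRI and simulation-derived features keep their group differences:
#' cohorts drawn from this specification separate the hybrid from the
#' clinical-only classifier.
#'
#' @return a `cohort_spec`
#' @export
model_effects_cohort_spec <- function() {
  spec <- default_cohort_spec()
  cl <- spec$provenance == "clinical"
  m <- (spec$m_resp + spec$m_non) / 2
  s <- ifelse(spec$kind == "continuous", sqrt((spec$s_resp^2 + spec$s_non^2) / 2), NA)
  spec$m_resp[cl] <- spec$m_non[cl] <- m[cl]
  spec$s_resp[cl] <- spec$s_non[cl] <- s[cl]
  spec
}

# truncated normal draw via inverse CDF
.rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd); phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic hybrid feature table
#'
#' Draws a latent responder label at the given prevalence, then features
#' from the group-conditional distributions of the specification
#' (independent within group), the echo block jointly missing for the
#' non-covered fraction of patients, and outcomes from the group-conditional
#' outcome model (EF change truncated so labels and outcomes agree under
#' the EF10 criterion).  The per-patient TAT/MTV normalized features are
#' derived from the drawn TAT and MTV.
#'
#' @param n number of patients (default 57)
#' @param prevalence responder prevalence (default 0.40)
#' @param spec a `cohort_spec` (default [default_cohort_spec()])
#' @param seed integer seed
#' @return a [cohort_table()]; the latent labels are in
#'   `attr(, "latent_label")`
#' @export
generate_feature_table <- function(n = 57, prevalence = 0.40,
                                   spec = default_cohort_spec(), seed = 1L) {
  stopifnot(prevalence > 0, prevalence < 1, n >= 2)
  if (any(spec$kind == "continuous" &
          (spec$s_resp <= 0 | spec$s_non <= 0)))
    stop("continuous feature SDs must be positive")
  set.seed(seed)
  lab <- rbinom(n, 1, prevalence)
  if (length(unique(lab)) < 2) {          # guarantee both groups at tiny n
    lab[1] <- 0L; lab[2] <- 1L
  }
  data <- list()
  for (j in seq_len(nrow(spec))) {
    m <- ifelse(lab == 1, spec$m_resp[j], spec$m_non[j])
    if (spec$kind[j] == "categorical") {
      data[[spec$name[j]]] <- rbinom(n, 1, m)
    } else {
      s <- ifelse(lab == 1, spec$s_resp[j], spec$s_non[j])
      data[[spec$name[j]]] <- rnorm(n, m, s)
    }
  }
  data <- as.data.frame(data)
  # volumes and times cannot be negative
  for (nm in c("MTV", "InfarctV", "TAT_LBBB", "TAT_BiV", "QRSd_LBBB",
               "QRSd_sim_LBBB", "QRSd_sim_BiV", "EDV", "ESV"))
    if (nm %in% names(data)) data[[nm]] <- pmax(data[[nm]], 1)
  if (all(c("TAT_LBBB", "MTV") %in% names(data))) {
    data$TAT_MTV_LBBB <- data$TAT_LBBB / data$MTV
    data$TAT_MTV_BiV <- data$TAT_BiV / data$MTV
  }
  echo <- spec$name[spec$echo_block]
  if (length(echo)) {
    avail <- rbinom(n, 1, attr(spec, "echo_avail")) == 1
    for (nm in echo) data[[nm]][!avail] <- NA
  }
  om <- attr(spec, "outcomes")
  de <- numeric(n)
  r <- lab == 1
  de[r] <- .rnorm_trunc(sum(r), om$delta_ef$m_resp, om$delta_ef$s_resp,
                        lower = om$delta_ef$truncate_at + 1e-9)
  de[!r] <- .rnorm_trunc(sum(!r), om$delta_ef$m_non, om$delta_ef$s_non,
                         upper = om$delta_ef$truncate_at)
  dv <- ifelse(r, rnorm(n, om$delta_esv$m_resp, om$delta_esv$s_resp),
               rnorm(n, om$delta_esv$m_non, om$delta_esv$s_non))
  meta <- data.frame(name = names(data), kind = "continuous",
                     provenance = "clinical", preop_safe = TRUE,
                     stringsAsFactors = FALSE)
  mi <- match(spec$name, meta$name)
  meta$kind[mi] <- spec$kind
  meta$provenance[mi] <- spec$provenance
  meta$provenance[meta$name %in% c("TAT_MTV_LBBB")] <- "sim_lbbb"
  meta$provenance[meta$name %in% c("TAT_MTV_BiV")] <- "sim_biv"
  ct <- cohort_table(data, meta, data.frame(delta_ef = de, delta_esv = dv))
  attr(ct, "latent_label") <- lab
  ct
}

#' Run the full EP pipeline for a set of synthetic patients
#'
#' For each patient: a randomized idealized anatomy (ellipsoid scale
#' jitter), an optional random LV lesion map, pacing-site placement, a
#' per-patient conductivity, LBBB activation through the Purkinje surrogate
#' and BiV pacing with zero inter-lead delay, 12-lead ECGs, and the full
#' biomarker set (per-mode indices, geometry/distance features, deltas).
#' Patients whose pipeline fails are skipped with a message.
#'
#' @param n number of synthetic patients
#' @param edge_length mesh edge length, mm (default 4)
#' @param lesion_prob probability that a patient carries a lesion map
#' @param g_range range of the per-patient conductivity scale (log-uniform)
#' @param prevalence responder prevalence for the sampled labels/outcomes
#' @param stencil solver stencil order
#' @param seed integer seed
#' @return list with `table` (a [cohort_table()] of model-derived features +
#'   sampled clinical columns) and `patients` (per-patient detail lists)
#' @export
generate_insilico_patients <- function(n = 10, edge_length = 4,
                                       lesion_prob = 0.7,
                                       g_range = c(0.5, 2), prevalence = 0.4,
                                       stencil = 2L, seed = 1L) {
  set.seed(seed)
  spec <- default_cohort_spec()
  torso <- torso_electrodes()
  lesion_pool <- list(septal = c(2L, 3L, 8L, 9L), inferior = c(4L, 10L, 15L),
                      lateral = c(5L, 6L, 11L, 12L), anterior = c(1L, 7L, 13L))
  rows <- list(); details <- list(); labs <- integer(0)
  skipped <- 0L
  for (i in seq_len(n)) {
    res <- tryCatch({
      sc <- runif(1, 0.9, 1.12)
      mesh <- build_ventricles(lv_inner_radii = c(42, 42, 52) * sc,
                               rv_inner_radii = c(36, 30, 42) * sc,
                               rv_center = c(33 * sc, 0, -5),
                               edge_length = edge_length, seed = seed + i)
      has_lesion <- runif(1) < lesion_prob
      if (has_lesion) {
        ischemic <- runif(1) < 0.5
        if (ischemic) {
          # post-infarction: non-excitable scar core (endo + mid layers) with
          # an intramural fibrosis border zone; fibrosis borders are kept off
          # the basal ring, where the idealized base truncation would seal
          # them into artificial slow pockets
          region <- lesion_pool[[sample.int(length(lesion_pool), 1)]]
          core <- sample(region, min(2L, length(region)))
          border <- setdiff(region[region > 6L], core)
          if (length(border)) border <- sample(border, min(2L, length(border)))
          spec_l <- lesion_spec(
            segment = c(rep(core, each = 2L), border),
            layer = c(rep(c("endo", "mid"), times = length(core)),
                      rep("mid", length(border))),
            class = c(rep("scar", 2L * length(core)),
                      rep("fibrosis", length(border))))
        } else {
          # non-ischemic remodeling: intramural (mid-layer) fibrosis in the
          # mid/apical septum
          segs <- sample(c(8L, 9L, 14L), sample(2:3, 1))
          spec_l <- lesion_spec(segs, "mid", "fibrosis")
        }
        mesh <- apply_lesions(mesh, spec_l)
      }
      mesh <- assign_fibers(mesh)
      pacing <- place_pacing_sites(mesh, lv_angle_deg = runif(1, 190, 230),
                                   lv_level = runif(1, 0.4, 0.6), seed = seed + i)
      g <- exp(runif(1, log(g_range[1]), log(g_range[2])))
      model <- conduction_model(g = g)
      tree <- grow_rv_tree(mesh, seed = seed + i)
      map_l <- solve_activation(mesh, model, lbbb_sources(tree),
                                stencil = stencil, mode = "LBBB")
      q_l <- measure_qrs(simulate_ecg(map_l, mesh, torso))
      bm_l <- compute_biomarkers(mesh, map_l, q_l)
      biv_src <- data.frame(node = c(pacing$rv_site, pacing$lv_site),
                            onset = c(0, pacing$rv_lv_delay))
      map_b <- solve_activation(mesh, model, biv_src,
                                stencil = stencil, mode = "BiV")
      q_b <- measure_qrs(simulate_ecg(map_b, mesh, torso))
      bm_b <- compute_biomarkers(mesh, map_b, q_b)
      lat <- late_activation_zone(map_l, mesh)
      geo <- geometry_features(mesh, pacing, lat, stencil = stencil)
      dl <- delta_features(bm_l, bm_b)
      list(mesh_summary = list(nodes = nrow(mesh$nodes), g = g, scale = sc,
                               pacing = pacing,
                               lesion = has_lesion,
                               lesion_map = if (has_lesion) spec_l else NULL),
           lbbb = bm_l, biv = bm_b, geometry = geo, delta = dl)
    }, error = function(e) {
      message(sprintf("patient %d skipped: %s", i, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) { skipped <- skipped + 1L; next }
    lab <- rbinom(1, 1, prevalence)
    labs <- c(labs, lab)
    cl_feats <- lapply(seq_len(nrow(spec)), function(j) {
      if (spec$provenance[j] != "clinical") return(NULL)
      m <- if (lab == 1) spec$m_resp[j] else spec$m_non[j]
      if (spec$kind[j] == "categorical") rbinom(1, 1, m)
      else rnorm(1, m, if (lab == 1) spec$s_resp[j] else spec$s_non[j])
    })
    names(cl_feats) <- spec$name
    cl_feats <- cl_feats[!vapply(cl_feats, is.null, TRUE)]
    row <- c(cl_feats, list(
      MTV = res$geometry$MTV, InfarctV = res$geometry$InfarctV,
      InfarctV_MTV = res$geometry$InfarctV_MTV,
      DLvRv = res$geometry$DLvRv, DLvLATZ = res$geometry$DLvLATZ,
      DLvInfarct = res$geometry$DLvInfarct,
      TAT_LBBB = res$lbbb$TAT, QRSd_sim_LBBB = res$lbbb$QRSd,
      AT_RVLV_LBBB = res$lbbb$AT_RVLV, IntAV_STLV_LBBB = res$lbbb$IntAV_STLV,
      mAT_STLV_LBBB = res$lbbb$mAT_STLV, TAT_MTV_LBBB = res$lbbb$TAT_MTV,
      TAT_BiV = res$biv$TAT, QRSd_sim_BiV = res$biv$QRSd,
      AT_RVLV_BiV = res$biv$AT_RVLV, IntAV_STLV_BiV = res$biv$IntAV_STLV,
      mAT_STLV_BiV = res$biv$mAT_STLV, TAT_MTV_BiV = res$biv$TAT_MTV,
      dTAT = res$delta$dTAT, dQRSd_sim = res$delta$dQRSd,
      dAT_RVLV = res$delta$dAT_RVLV, dIntAV_STLV = res$delta$dIntAV_STLV,
      dmAT_STLV = res$delta$dmAT_STLV))
    rows[[length(rows) + 1L]] <- as.data.frame(row)
    details[[length(details) + 1L]] <- res
  }
  if (!length(rows)) stop("all patients failed")
  if (skipped) message(sprintf("%d of %d patients skipped", skipped, n))
  data <- do.call(rbind, rows)
  meta <- data.frame(name = names(data), kind = "continuous",
                     provenance = "clinical", preop_safe = TRUE,
                     stringsAsFactors = FALSE)
  mi <- match(spec$name, meta$name)
  ok <- !is.na(mi)
  meta$kind[mi[ok]] <- spec$kind[ok]
  meta$provenance[mi[ok]] <- spec$provenance[ok]
  meta$provenance[grepl("_BiV$|_sim_BiV$", meta$name)] <- "sim_biv"
  meta$provenance[grepl("_LBBB$", meta$name)] <- "sim_lbbb"
  meta$provenance[meta$name %in% c("MTV", "InfarctV", "InfarctV_MTV",
                                   "DLvRv", "DLvLATZ", "DLvInfarct")] <- "ctmri_model"
  meta$provenance[meta$name %in% c("QRSd_LBBB", "EF_LBBB")] <- "clinical"
  meta$provenance[grepl("^d", meta$name) &
                  meta$name %in% c("dTAT", "dQRSd_sim", "dAT_RVLV",
                                   "dIntAV_STLV", "dmAT_STLV")] <- "sim_delta"
  om <- attr(spec, "outcomes")
  nr <- length(labs)
  de <- numeric(nr)
  de[labs == 1] <- .rnorm_trunc(sum(labs == 1), om$delta_ef$m_resp,
                                om$delta_ef$s_resp, lower = om$delta_ef$truncate_at + 1e-9)
  de[labs == 0] <- .rnorm_trunc(sum(labs == 0), om$delta_ef$m_non,
                                om$delta_ef$s_non, upper = om$delta_ef$truncate_at)
  dv <- ifelse(labs == 1, rnorm(nr, om$delta_esv$m_resp, om$delta_esv$s_resp),
               rnorm(nr, om$delta_esv$m_non, om$delta_esv$s_non))
  ct <- cohort_table(data, meta, data.frame(delta_ef = de, delta_esv = dv))
  attr(ct, "latent_label") <- labs
  list(table = ct, patients = details, skipped = skipped)
}
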