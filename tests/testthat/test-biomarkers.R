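test_that("TAT is the span of finite activation times", {
  m <- fx_heart()
  n <- nrow(m$nodes)
  expect_equal(tat(fake_map(seq(0, 141, length.out = n))), 141)
  expect_equal(tat(fake_map(rep(33, n))), 0)
  set.seed(9)
  at <- runif(n, 10, 400)
  at[1:5] <- Inf
  expect_equal(tat(fake_map(at)), max(at[-(1:5)]) - min(at[-(1:5)]))
})

test_that("AT_RVLV subtracts the per-chamber late activation times with sign", {
  m <- fx_heart()
  at <- numeric(nrow(m$nodes))
  lv <- m$node_wall %in% c("LV_free", "septum")
  at[lv] <- 100; at[!lv] <- 80
  at[which(lv)[1]] <- 246
  at[which(!lv)[1]] <- 143
  expect_equal(at_rvlv(fake_map(at), m), 103)
  # mirror-symmetric activation
  expect_equal(at_rvlv(fake_map(rep(60, nrow(m$nodes))), m), 0)
  # random map against a label-scan oracle
  set.seed(2)
  atr <- runif(nrow(m$nodes), 0, 300)
  expect_equal(at_rvlv(fake_map(atr), m),
               max(atr[lv]) - max(atr[m$node_wall == "RV_free"]))
})

test_that("mAT_STLV is the normalized volume-weighted mean difference", {
  m <- fx_heart()
  at <- numeric(nrow(m$nodes))
  at[m$node_wall == "LV_free"] <- 100
  at[m$node_wall == "septum"] <- 64
  at[m$node_wall == "RV_free"] <- 0      # makes TAT = 100
  expect_equal(mat_stlv(fake_map(at), m), 0.36)
  # identical means cancel
  at2 <- at; at2[m$node_wall == "septum"] <- 100
  expect_equal(mat_stlv(fake_map(at2), m), 0)
  # degenerate TAT = 0 is NA-flagged
  expect_true(is.na(mat_stlv(fake_map(rep(7, nrow(m$nodes))), m)))
  # random map against an independently computed volume-weighted oracle
  set.seed(3)
  atr <- runif(nrow(m$nodes), 0, 250)
  w <- numeric(nrow(m$nodes))
  keep <- m$tissue_class != "scar"
  for (k in 1:4) {
    idx <- m$tets[keep, k]
    w <- w + unname(vapply(split(m$elem_volume[keep] / 4,
                                 factor(idx, levels = seq_len(nrow(m$nodes)))),
                           sum, 0))
  }
  wm <- function(sel) sum(atr[sel] * w[sel]) / sum(w[sel])
  oracle <- (wm(m$node_wall == "LV_free") - wm(m$node_wall == "septum")) /
    (max(atr) - min(atr))
  expect_equal(mat_stlv(fake_map(atr), m), oracle, tolerance = 1e-12)
  # unweighted mode uses plain node means
  oracle_u <- (mean(atr[m$node_wall == "LV_free"]) -
               mean(atr[m$node_wall == "septum"])) / (max(atr) - min(atr))
  expect_equal(mat_stlv(fake_map(atr), m, weighted = FALSE), oracle_u,
               tolerance = 1e-12)
})

test_that("IntAV_STLV integrates the absolute fraction difference (quadrature oracle)", {
  # closed form: integral of |t/100 - (t/100)^2| over [0, 100] = 50 - 100/3
  t <- seq(0, 100, by = 1)
  f1 <- t / 100; f2 <- (t / 100)^2
  val <- crtsim:::.abs_diff_integral(t, f1, f2)
  expect_equal(val, 50 - 100 / 3, tolerance = 0.01 * (50 - 100 / 3))
  expect_equal(val, pracma::trapz(t, abs(f1 - f2)), tolerance = 1e-12)
  expect_equal(crtsim:::.abs_diff_integral(t, f1, f1), 0)
  # synchronized regions give a zero integral (the LV activates as one block;
  # an RV-interior node supplies the nonzero span)
  m <- fx_heart()
  at <- rep(40, nrow(m$nodes))
  rv_only <- setdiff(unique(as.vector(m$tets[m$wall_label == "RV_free", ])),
                     unique(as.vector(m$tets[m$wall_label != "RV_free", ])))
  at[rv_only[1]] <- 0
  expect_equal(intav_stlv(fake_map(at), m), 0)
})

test_that("activated-volume curves are monotone and saturate at the region volumes", {
  m <- fx_heart()
  map <- fx_lbbb()
  cv <- activation_volume_curves(map, m)
  expect_true(all(diff(cv$av_st) >= 0))
  expect_true(all(diff(cv$av_lat) >= 0))
  expect_equal(cv$av_st[length(cv$av_st)], cv$v_st)
  expect_equal(cv$av_lat[length(cv$av_lat)], cv$v_lat)
  expect_equal(cv$v_st, sum(m$elem_volume[m$wall_label == "septum"]))
  # quadrature refinement changes the smooth-map integral by < 1%
  i1 <- intav_stlv(map, m, dt = 1)
  i05 <- intav_stlv(map, m, dt = 0.5)
  expect_lt(abs(i1 - i05) / i05, 0.01)
})

test_that("geometry features: volumes, distances, and missing-value semantics", {
  m <- fx_heart()
  pc <- place_pacing_sites(m)
  gf <- geometry_features(m, pc)
  expect_equal(gf$MTV * 1000, sum(m$elem_volume))       # summation oracle
  expect_equal(gf$InfarctV, 0)
  expect_true(is.na(gf$DLvInfarct))                     # no lesion -> NA, not 0
  expect_true(is.na(gf$DLvLATZ))
  expect_gt(gf$DLvRv, 0)
  ml <- apply_lesions(m, lesion_spec(c(8, 9), "mid", "fibrosis"))
  gfl <- geometry_features(ml, pc)
  expect_equal(gfl$InfarctV * 1000, sum(ml$elem_volume[ml$tissue_class == "fibrosis"]))
  expect_equal(gfl$MTV, gf$MTV)                         # fibrosis stays in MTV
  expect_gt(gfl$DLvInfarct, 0)
  # LV site inside the lesion region -> zero distance
  lesion_nodes <- unique(as.vector(ml$tets[ml$tissue_class == "fibrosis", ]))
  pc0 <- pc; pc0$lv_site <- lesion_nodes[1]
  expect_equal(geometry_features(ml, pc0)$DLvInfarct, 0)
  # scar is excluded from MTV but counted in InfarctV
  ms <- apply_lesions(m, lesion_spec(c(8, 9), "mid", "scar"))
  gfs <- geometry_features(ms, pc)
  expect_equal(gfs$MTV * 1000, sum(ms$elem_volume[ms$tissue_class != "scar"]))
  expect_equal(gfs$InfarctV, gfl$InfarctV)
})

test_that("delta features use relative percent changes except the normalized index", {
  lbbb <- list(TAT = 100, QRSd = 192, mAT_STLV = 0.36, AT_RVLV = 50)
  biv <- list(TAT = 100, QRSd = 143, mAT_STLV = 0.29, AT_RVLV = 50)
  d <- delta_features(lbbb, biv)
  expect_equal(d$dQRSd, 100 * (143 - 192) / 192)         # -25.5%
  expect_equal(d$dQRSd, -25.5, tolerance = 0.01)
  expect_equal(d$dmAT_STLV, -0.07)                       # absolute increment
  expect_equal(d$dTAT, 0)
  expect_equal(d$dAT_RVLV, 0)
  expect_true(is.na(delta_features(list(TAT = 0), list(TAT = 10))$dTAT))
  expect_true(is.na(delta_features(list(TAT = NA_real_), list(TAT = 10))$dTAT))
})

test_that("all activation indices are invariant to a global time shift", {
  m <- fx_heart()
  map <- fx_lbbb()
  sh <- fake_map(map$at + 37)
  expect_equal(tat(sh), tat(map), tolerance = 1e-9)
  expect_equal(at_rvlv(sh, m), at_rvlv(map, m), tolerance = 1e-9)
  expect_equal(mat_stlv(sh, m), mat_stlv(map, m), tolerance = 1e-9)
  expect_equal(intav_stlv(sh, m), intav_stlv(map, m), tolerance = 1e-9)
})

test_that("the assembled biomarker set is internally consistent", {
  m <- fx_heart()
  map <- fx_lbbb()
  q <- measure_qrs(simulate_ecg(map, m, torso_electrodes()))
  bm <- compute_biomarkers(m, map, q)
  mtv <- sum(m$elem_volume) / 1000
  expect_equal(bm$TAT_MTV, bm$TAT / mtv)
  expect_equal(bm$QRSd, q$qrsd)
  expect_equal(bm$TAT, tat(map))
})
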