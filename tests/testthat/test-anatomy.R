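test_that("default anatomy populates all 51 LV (segment, layer) regions with a clean label partition", {
  m <- fx_heart()
  lv <- m$aha_segment > 0
  codes <- unique(paste(m$aha_segment[lv], m$layer_label[lv]))
  expect_length(codes, 51)
  expect_true(all(m$wall_label %in% c("LV_free", "septum", "RV_free")))
  expect_true(all(m$layer_label %in% c("endo", "mid", "epi")))
  expect_true(all(m$tissue_class == "normal"))
  expect_true(all(m$aha_segment[m$wall_label == "RV_free"] == 0))
  expect_true(all(m$aha_segment[m$wall_label != "RV_free"] %in% 1:17))
  expect_true(all(m$elem_volume > 0))
  expect_equal(max(abs(m$elem_volume - m$h^3 / 6)), 0)
})

test_that("mesh volume matches the analytic ellipsoid-shell volume within 5%", {
  m <- fx_heart()
  g <- m$geom
  lv_analytic <- 2 / 3 * pi * (prod(g$lv_outer) - prod(g$lv_inner))
  lv_mesh <- sum(m$elem_volume[m$wall_label != "RV_free"])
  expect_lt(abs(lv_mesh - lv_analytic) / lv_analytic, 0.05)
})

test_that("coarser meshes have fewer nodes but the same label taxonomy", {
  fine <- fx_heart()
  coarse <- build_ventricles(edge_length = 8)
  expect_lt(nrow(coarse$nodes), nrow(fine$nodes))
  expect_setequal(unique(coarse$wall_label), unique(fine$wall_label))
  expect_setequal(unique(coarse$layer_label), unique(fine$layer_label))
})

test_that("mesh construction is deterministic", {
  a <- build_ventricles(edge_length = 8, seed = 5L)
  b <- build_ventricles(edge_length = 8, seed = 5L)
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$tets, b$tets)
  expect_identical(a$wall_label, b$wall_label)
  expect_identical(a$aha_segment, b$aha_segment)
})

test_that("degenerate shape parameters are rejected", {
  expect_error(build_ventricles(lv_wall = -1), "positive")
  expect_error(build_ventricles(edge_length = 0), "positive")
  expect_error(build_ventricles(lv_wall = 60), "smaller than radii")
})

test_that("fibers are unit-norm, tangent to the wall, with the linear helix rule", {
  m <- fx_heart()
  expect_lt(max(abs(sqrt(rowSums(m$fiber^2)) - 1)), 1e-9)
  # oracle: transmural normals from the ellipsoid parameterization
  g <- m$geom
  x <- m$elem_center
  lv <- m$wall_label != "RV_free"
  e <- function(p, r, c0 = c(0, 0, 0))
    sqrt(((p[, 1] - c0[1]) / r[1])^2 + ((p[, 2] - c0[2]) / r[2])^2 +
         ((p[, 3] - c0[3]) / r[3])^2)
  grad <- function(p, r, c0 = c(0, 0, 0)) {
    ee <- e(p, r, c0)
    cbind((p[, 1] - c0[1]) / r[1]^2, (p[, 2] - c0[2]) / r[2]^2,
          (p[, 3] - c0[3]) / r[3]^2) / ee
  }
  nrm <- grad(x, g$lv_inner) + grad(x, g$lv_outer)
  nrm[!lv, ] <- (grad(x, g$rv_inner, g$rv_center) +
                 grad(x, g$rv_outer, g$rv_center))[!lv, ]
  nrm <- nrm / sqrt(rowSums(nrm^2))
  expect_lt(mean(abs(rowSums(m$fiber * nrm))), 0.1)
  # helix angle endpoints and midpoint (checked against the depth rule)
  zhat <- c(0, 0, 1)
  circ <- cbind(-nrm[, 2], nrm[, 1], 0)
  circ <- circ / pmax(sqrt(rowSums(circ^2)), 1e-12)
  long <- cbind(nrm[, 2] * circ[, 3] - nrm[, 3] * circ[, 2],
                nrm[, 3] * circ[, 1] - nrm[, 1] * circ[, 3],
                nrm[, 1] * circ[, 2] - nrm[, 2] * circ[, 1])
  ang <- atan2(rowSums(m$fiber * long), rowSums(m$fiber * circ)) * 180 / pi
  expected <- 60 - 120 * m$depth
  ok <- abs(circ[, 3]) < 0.9          # away from the apex singularity
  expect_lt(max(abs(ang - expected)[ok]), 1)
  mid <- which(abs(m$depth - 0.5) < 0.02 & ok)
  expect_lt(max(abs(ang[mid])), 3)    # mid-depth fibers are circumferential
})

test_that("lesion maps set tissue classes per (segment, layer) and report volumes", {
  m <- fx_heart()
  sp <- lesion_spec(c(2, 3, 8, 9), "mid", "fibrosis")
  ml <- apply_lesions(m, sp)
  hit <- ml$aha_segment %in% c(2, 3, 8, 9) & ml$layer_label == "mid"
  expect_true(all(ml$tissue_class[hit] == "fibrosis"))
  expect_true(all(ml$tissue_class[!hit] == "normal"))
  # brute-force volume oracle
  vol_brute <- sum(ml$elem_volume[which(ml$tissue_class == "fibrosis")])
  gf <- geometry_features(ml, place_pacing_sites(ml))
  expect_equal(gf$InfarctV * 1000, vol_brute)
  # empty spec resets everything to normal
  m0 <- apply_lesions(ml, lesion_spec())
  expect_true(all(m0$tissue_class == "normal"))
})

test_that("invalid lesion specifications are rejected", {
  expect_error(lesion_spec(18, "mid", "scar"), "1-17")
  expect_error(lesion_spec(0, "mid", "scar"), "1-17")
  expect_error(lesion_spec(3, "outer", "scar"), "endo, mid or epi")
  expect_error(lesion_spec(3, "mid", "edema"), "fibrosis or scar")
})

test_that("the mesh stays edge-connected after removing scar elements", {
  m <- apply_lesions(fx_heart(), lesion_spec(c(5, 5, 6, 6), c("endo", "mid"),
                                             "scar"))
  gph <- edge_graph(m, "iso", stencil = 1L, exclude_scar = TRUE)
  live_nodes <- unique(c(gph$from, gph$to))
  d <- geodesic_distance(m, live_nodes[1], live_nodes, exclude_scar = TRUE,
                         stencil = 1L)
  expect_true(is.finite(d))
  at <- dijkstra_oracle(nrow(m$nodes), gph$from, gph$to, gph$len,
                        live_nodes[1], 0)
  expect_true(all(is.finite(at[live_nodes])))
})

test_that("pacing sites follow the apex and lateral-wall rules deterministically", {
  m <- fx_heart()
  pc <- place_pacing_sites(m)
  rv_endo <- m$surfaces$endo_rv
  expect_true(pc$rv_site %in% rv_endo)
  expect_equal(m$nodes[pc$rv_site, 3], min(m$nodes[rv_endo, 3]))
  expect_true(m$node_aha[pc$lv_site] %in% c(5, 6, 11, 12))
  expect_equal(m$node_wall[pc$lv_site], "LV_free")
  expect_equal(pc$rv_lv_delay, 0)
  pc2 <- place_pacing_sites(m)
  expect_identical(pc[c("rv_site", "lv_site")], pc2[c("rv_site", "lv_site")])
})

test_that("an LV pacing target on scar is moved to the nearest non-scar node", {
  m <- fx_heart()
  pc0 <- place_pacing_sites(m)
  seg <- m$node_aha[pc0$lv_site]
  ml <- apply_lesions(m, lesion_spec(rep(seg, 3), c("endo", "mid", "epi"), "scar"))
  expect_warning(pc <- place_pacing_sites(ml), "scar")
  expect_false(crtsim:::.node_on_scar(ml)[pc$lv_site])
})

test_that("torso electrodes are distinct and outside the ventricles", {
  el <- torso_electrodes()$electrodes
  expect_equal(rownames(el), c("RA", "LA", "LL", paste0("V", 1:6)))
  expect_equal(nrow(unique(el)), 9)
  m <- fx_heart()
  bb_lo <- apply(m$nodes, 2, min); bb_hi <- apply(m$nodes, 2, max)
  inside <- apply(el, 1, function(p) all(p >= bb_lo & p <= bb_hi))
  expect_false(any(inside))
})
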