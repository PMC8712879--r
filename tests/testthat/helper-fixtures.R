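# Shared fixtures, memoized across test files (meshes carry their own edge
# graph caches, so reuse also avoids rebuilding graphs).

.fx <- new.env()

fx_heart <- function() {
  if (is.null(.fx$heart)) .fx$heart <- assign_fibers(build_ventricles())
  .fx$heart
}

fx_slab <- function(lx = 40, ly = 40, lz = 12, h = 4) {
  key <- sprintf("slab_%g_%g_%g_%g", lx, ly, lz, h)
  if (is.null(.fx[[key]])) .fx[[key]] <- build_slab_mesh(lx, ly, lz, h)
  .fx[[key]]
}

fx_lbbb <- function() {
  if (is.null(.fx$lbbb)) {
    m <- fx_heart()
    tree <- grow_rv_tree(m)
    .fx$lbbb <- solve_activation(m, conduction_model(), lbbb_sources(tree),
                                 mode = "LBBB")
  }
  .fx$lbbb
}

fx_biv <- function() {
  if (is.null(.fx$biv)) {
    m <- fx_heart()
    pc <- place_pacing_sites(m)
    .fx$biv <- solve_activation(m, conduction_model(),
                                data.frame(node = c(pc$rv_site, pc$lv_site),
                                           onset = 0), mode = "BiV")
  }
  .fx$biv
}

# synthetic activation map over a mesh (for biomarker arithmetic tests)
fake_map <- function(at, mode = "custom") {
  structure(list(at = at, sources = data.frame(node = 1L, onset = 0),
                 mode = mode), class = "activation_map")
}

# independent SSSP oracle on an exported edge list (igraph implementation)
dijkstra_oracle <- function(n, from, to, w, src, onset) {
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  d <- igraph::distances(g, v = src, weights = w)
  apply(d + onset, 2, min)
}

# brute-force ROC AUC: fraction of concordant (case, control) score pairs,
# ties counted 1/2
auc_oracle <- function(labels, scores) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# clinical-only view of a cohort table
clinical_subset <- function(ct) {
  keep <- ct$meta$name[ct$meta$provenance == "clinical"]
  cohort_table(ct$data[keep], ct$meta[ct$meta$name %in% keep, ], ct$outcomes)
}
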