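# Right-sided His-Purkinje surrogate for the LBBB activation mode.
#
# In left bundle branch block the left conduction system is silent: the
# ventricles are engaged through the right bundle only.  The surrogate is a
# deterministic fractal tree grown on the RV endocardial surface: a trunk
# from a septal origin toward the RV apex (the right bundle), then recursive
# binary branching.  The tree is insulated from the working myocardium and
# couples only at its terminals (Purkinje-myocardial junctions, PMJs); each
# PMJ fires at (tree path length from the origin) / conduction velocity.

# real tetrahedral edges restricted to a node subset, as adjacency list
.surface_adjacency <- function(mesh, node_set) {
  tets <- mesh$tets
  pairs <- rbind(tets[, c(1, 2)], tets[, c(1, 3)], tets[, c(1, 4)],
                 tets[, c(2, 3)], tets[, c(2, 4)], tets[, c(3, 4)])
  keep <- pairs[, 1] %in% node_set & pairs[, 2] %in% node_set
  pairs <- pairs[keep, , drop = FALSE]
  a <- pmin(pairs[, 1], pairs[, 2]); b <- pmax(pairs[, 1], pairs[, 2])
  key <- a * (nrow(mesh$nodes) + 1) + b
  u <- !duplicated(key)
  list(from = a[u], to = b[u])
}

.adj_list <- function(edges, nodes) {
  adj <- vector("list", nodes)
  ff <- c(edges$from, edges$to)
  tt <- c(edges$to, edges$from)
  sp <- split(tt, ff)
  adj[as.integer(names(sp))] <- sp
  adj
}

# single-source Dijkstra with predecessors on a small graph (R implementation,
# used only for the surface trunk path)
.dijkstra_path <- function(adj, coords, from, to) {
  n <- length(adj)
  dist <- rep(Inf, n); prev <- rep(NA_integer_, n)
  dist[from] <- 0
  done <- rep(FALSE, n)
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!length(u) || !is.finite(dist[u])) break
    if (u == to) break
    done[u] <- TRUE
    for (v in adj[[u]]) {
      if (done[v]) next
      nd <- dist[u] + sqrt(sum((coords[v, ] - coords[u, ])^2))
      if (nd < dist[v]) { dist[v] <- nd; prev[v] <- u }
    }
    if (all(done | !is.finite(dist))) break
  }
  if (!is.finite(dist[to])) return(NULL)
  path <- to
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  list(path = path, dist = dist[to])
}

.rodrigues <- function(v, axis, theta) {
  k <- axis / sqrt(sum(axis^2))
  v * cos(theta) + c(k[2] * v[3] - k[3] * v[2],
                     k[3] * v[1] - k[1] * v[3],
                     k[1] * v[2] - k[2] * v[1]) * sin(theta) +
    k * sum(k * v) * (1 - cos(theta))
}

#' Grow the RV His-Purkinje surrogate tree
#'
#' A ~`bundle_length` mm trunk runs from a septal origin node over the RV
#' endocardial surface toward the RV apex, then splits into a binary tree of
#' `generations` levels with branches of `branch_length` mm deflected by
#' `branch_angle` degrees about the local surface normal.  Terminal tips are
#' the PMJs; their onset times are the tree path length divided by the
#' His-Purkinje conduction velocity (3 mm/ms).
#'
#' @param mesh a biventricular `ventricular_mesh`
#' @param bundle_length trunk length, mm (right bundle, default 40)
#' @param branch_length branch segment length per generation, mm
#' @param branch_angle branching half-angle, degrees
#' @param generations binary branching depth (2^generations terminal tips)
#' @param velocity His-Purkinje conduction velocity, mm/ms
#' @param seed recorded; growth is deterministic
#' @return a `purkinje_tree`: list with `origin`, `segments` (data frame of
#'   from/to node paths) and `pmj` (data frame `node`, `onset`, `path_length`)
#' @export
grow_rv_tree <- function(mesh, bundle_length = 40, branch_length = 8,
                         branch_angle = 20, generations = 6, velocity = 3,
                         seed = 1L) {
  if (mesh$kind != "biventricular") stop("the Purkinje surrogate needs the biventricular geometry")
  stopifnot(velocity > 0, generations >= 1, branch_length > 0)
  surf <- mesh$surfaces$endo_rv
  if (!length(surf)) stop("RV endocardial surface is empty")
  edges <- .surface_adjacency(mesh, surf)
  adj <- .adj_list(edges, nrow(mesh$nodes))
  coords <- mesh$nodes

  sept <- surf[mesh$node_wall[surf] == "septum"]
  if (!length(sept)) sept <- surf
  origin <- sept[order(-coords[sept, 3], sept)][1]     # most basal septal node
  apex <- surf[order(coords[surf, 3], surf)][1]

  trunk <- .dijkstra_path(adj, coords, origin, apex)
  if (is.null(trunk)) stop("RV endocardial surface is disconnected")
  # truncate the trunk at bundle_length (or at the apex, whichever first)
  path <- trunk$path
  seglen <- sqrt(rowSums((coords[path[-1], , drop = FALSE] -
                          coords[path[-length(path)], , drop = FALSE])^2))
  cum <- cumsum(seglen)
  stop_at <- which(cum >= bundle_length)[1]
  if (is.na(stop_at)) stop_at <- length(seglen)
  path <- path[1:(stop_at + 1)]
  trunk_len <- cum[stop_at]
  tip0 <- path[length(path)]
  dir0 <- coords[tip0, ] - coords[path[length(path) - 1], ]
  dir0 <- dir0 / sqrt(sum(dir0^2))

  g <- mesh$geom
  surface_normal <- function(node) {
    x <- matrix(coords[node, ], 1)
    nrm <- .ellipsoid_grad(x, g$rv_inner, g$rv_center)[1, ]
    nrm / sqrt(sum(nrm^2))
  }
  walk_branch <- function(start, dvec, len) {
    u <- start; total <- 0; last_dir <- dvec
    while (total < len) {
      nb <- adj[[u]]
      if (!length(nb)) break
      steps <- coords[nb, , drop = FALSE] - matrix(coords[u, ], length(nb), 3, byrow = TRUE)
      stepn <- sqrt(rowSums(steps^2))
      cosd <- (steps %*% dvec)[, 1] / stepn
      ok <- which(cosd > 0.05)
      if (!length(ok)) break
      pick <- ok[order(-cosd[ok], nb[ok])][1]
      last_dir <- steps[pick, ] / stepn[pick]
      total <- total + stepn[pick]
      u <- nb[pick]
    }
    list(node = u, len = total, dir = last_dir)
  }

  tips <- list(list(node = tip0, dir = dir0, plen = trunk_len))
  segments <- data.frame(from = path[-length(path)], to = path[-1])
  theta <- branch_angle * pi / 180
  for (gen in seq_len(generations)) {
    nxt <- vector("list", 2 * length(tips))
    k <- 0
    for (tp in tips) {
      nrm <- surface_normal(tp$node)
      for (sg in c(-1, 1)) {
        dnew <- .rodrigues(tp$dir, nrm, sg * theta)
        dnew <- dnew - sum(dnew * nrm) * nrm      # keep tangent
        dnew <- dnew / max(sqrt(sum(dnew^2)), 1e-12)
        br <- walk_branch(tp$node, dnew, branch_length)
        k <- k + 1
        nxt[[k]] <- list(node = br$node, dir = br$dir, plen = tp$plen + br$len)
        if (br$node != tp$node)
          segments <- rbind(segments, data.frame(from = tp$node, to = br$node))
      }
    }
    tips <- nxt[seq_len(k)]
  }

  node_scar <- .node_on_scar(mesh)
  pmj_node <- vapply(tips, `[[`, 0L, "node")
  pmj_len <- vapply(tips, `[[`, 0, "plen")
  on_scar <- node_scar[pmj_node]
  if (any(on_scar)) {
    warning(sprintf("%d PMJ tips on scar discarded", sum(on_scar)))
    pmj_node <- pmj_node[!on_scar]; pmj_len <- pmj_len[!on_scar]
  }
  if (!length(pmj_node)) stop("no valid PMJs")
  structure(list(origin = origin, apex = apex, trunk = path,
                 segments = segments, velocity = velocity,
                 pmj = data.frame(node = pmj_node, onset = pmj_len / velocity,
                                  path_length = pmj_len),
                 params = list(bundle_length = bundle_length,
                               branch_length = branch_length,
                               branch_angle = branch_angle,
                               generations = generations, seed = as.integer(seed))),
            class = "purkinje_tree")
}

#' PMJ boundary conditions for the LBBB activation mode
#'
#' The His system couples to the working myocardium only at the PMJs, so the
#' LBBB sources are exactly the PMJ (node, onset) pairs; there is no
#' left-sided tree.
#'
#' @param tree a `purkinje_tree`
#' @return data frame with `node`, `onset` columns for [solve_activation()]
#' @export
lbbb_sources <- function(tree) {
  if (!nrow(tree$pmj)) stop("tree has no PMJs")
  tree$pmj[, c("node", "onset")]
}

#' @export
print.purkinje_tree <- function(x, ...) {
  cat(sprintf("purkinje_tree: origin %d, %d PMJs, onsets %.1f-%.1f ms (v = %g mm/ms)\n",
              x$origin, nrow(x$pmj), min(x$pmj$onset), max(x$pmj$onset), x$velocity))
  invisible(x)
}
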