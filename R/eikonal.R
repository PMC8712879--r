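# Anisotropic Eikonal activation and isotropic geodesic distances.

#' Conduction model parameters
#'
#' Cardiac tissue is an anisotropic conductor with conductivity ratio `rho`
#' along vs across the fibers; velocity scales with the square root of
#' conductivity, so `rho = 4` gives the physiological 2:1 velocity ratio.
#' The global dimensionless conductivity scale `g` multiplies the reference
#' conductivity, hence the along-fiber speed is `v_f = v0 * sqrt(g)` and the
#' cross-fiber speed `v_t = v_f / sqrt(rho)`.  Fibrosis conducts at
#' `fibrosis_fraction` (default 1%) of the local conductivity, i.e. at 10%
#' of the local speed; scar does not conduct at all.
#'
#' @param g global conductivity scale (dimensionless), default 1
#' @param v0 along-fiber conduction velocity at `g = 1`, mm/ms
#' @param rho along:across conductivity ratio, default 4
#' @param fibrosis_fraction conductivity fraction of fibrotic tissue
#' @return a `conduction_model` list with derived speeds `v_f`, `v_t`
#' @export
conduction_model <- function(g = 1, v0 = 0.6, rho = 4, fibrosis_fraction = 0.01) {
  stopifnot(g > 0, v0 > 0, rho >= 1, fibrosis_fraction > 0, fibrosis_fraction <= 1)
  vf <- v0 * sqrt(g)
  structure(list(g = g, v0 = v0, rho = rho,
                 fibrosis_fraction = fibrosis_fraction,
                 v_f = vf, v_t = vf / sqrt(rho)),
            class = "conduction_model")
}

#' Solve the anisotropic first-arrival (Eikonal) problem
#'
#' Computes the activation time at every mesh node as the first arrival of a
#' front propagating under the anisotropic (Riemannian) speed metric with ray
#' speed `v(d) = (cos^2/v_f^2 + sin^2/v_t^2)^(-1/2)` for a path direction `d`
#' at angle `acos(|d.f|)` to the local fiber `f` -- the metric whose point
#' response is the elliptical norm `sqrt(x' D^-1 x)`,
#' `D = v_f^2 f f' + v_t^2 (I - f f')` -- from a set of source nodes with
#' individual onset times
#' (the pacing boundary condition).  Realized as multi-source Dijkstra on
#' the stencil edge graph; scar is excluded from the propagation domain and
#' scar-isolated nodes keep an infinite activation time.
#'
#' @param mesh a `ventricular_mesh` with fibers
#' @param model a [conduction_model()]
#' @param sources data frame (or 2-column matrix) of `node`, `onset` (ms)
#' @param stencil stencil order of the edge graph, see [edge_graph()]
#' @return an `activation_map`: list with `at` (ms per node, `Inf` where
#'   unreachable), `sources`, `mode` tag
#' @export
solve_activation <- function(mesh, model, sources, stencil = 2L, mode = "custom",
                             stencil_aspect = c(1, 1, 1)) {
  sources <- as.data.frame(sources)
  names(sources)[1:2] <- c("node", "onset")
  if (!nrow(sources)) stop("at least one source is required")
  scar_node <- .node_on_scar(mesh)
  live <- !scar_node[sources$node]
  if (!any(live)) stop("all sources lie on scar tissue")
  sources <- sources[live, , drop = FALSE]
  gph <- edge_graph(mesh, "aniso", model = model, stencil = stencil,
                    stencil_aspect = stencil_aspect)
  w <- gph$len / (model$v_f * gph$sfac)
  at <- dijkstra_first_arrival(nrow(mesh$nodes), gph$from, gph$to, w,
                               as.integer(sources$node), sources$onset)
  if (any(!is.finite(at) & !scar_node[seq_along(at)] &
          tabulate(as.vector(mesh$tets), nbins = length(at)) > 0))
    warning("disconnected non-scar region: some nodes keep infinite activation time")
  structure(list(at = at, sources = sources, mode = mode, model = model),
            class = "activation_map")
}

#' Ruler-like geodesic distance on the mesh, mm
#'
#' First-arrival value of an isotropic unit-speed Eikonal solve from
#' `from_node`, minimized over `to_region`.  Scar elements are part of the
#' domain by default: the value mimics a distance measured on CT/MRI images
#' with a ruler, which does not know about excitability.
#'
#' @param mesh a `ventricular_mesh`
#' @param from_node source node index
#' @param to_region integer vector of target node indices
#' @param exclude_scar drop scar elements from the domain (off by default)
#' @param stencil stencil order, see [edge_graph()]
#' @return distance in mm (Inf if unreachable)
#' @export
geodesic_distance <- function(mesh, from_node, to_region,
                              exclude_scar = FALSE, stencil = 2L) {
  if (!length(to_region)) stop("to_region is empty")
  gph <- edge_graph(mesh, "iso", stencil = stencil, exclude_scar = exclude_scar)
  d <- dijkstra_first_arrival(nrow(mesh$nodes), gph$from, gph$to, gph$len,
                              as.integer(from_node), 0)
  min(d[to_region])
}

#' Late activation zone of an activation map
#'
#' Nodes activating in the last `(1 - fraction)` of the total activation
#' span, restricted to the LV (free wall + septum) -- the candidate target
#' region for LV lead placement.
#'
#' @param map an `activation_map`
#' @param mesh the mesh the map was computed on
#' @param fraction threshold fraction of the activation span (default 0.9:
#'   the latest decile)
#' @return integer vector of node indices
#' @export
late_activation_zone <- function(map, mesh, fraction = 0.9) {
  stopifnot(fraction >= 0, fraction <= 1)
  at <- map$at
  fin <- is.finite(at)
  if (!any(fin)) stop("activation map has no finite values")
  lo <- min(at[fin]); hi <- max(at[fin])
  thr <- lo + fraction * (hi - lo)
  lv <- mesh$node_wall %in% c("LV_free", "septum")
  which(fin & at >= thr & lv)
}

#' Total activation time (TAT), ms
#' @param map an `activation_map`
#' @return `AT_max - AT_min` over finite nodes
#' @export
tat <- function(map) {
  at <- map$at[is.finite(map$at)]
  if (!length(at)) stop("activation map has no finite values")
  max(at) - min(at)
}

#' @export
print.activation_map <- function(x, ...) {
  fin <- is.finite(x$at)
  cat(sprintf("activation_map [%s]: %d nodes (%d reached), TAT = %.1f ms\n",
              x$mode, length(x$at), sum(fin), max(x$at[fin]) - min(x$at[fin])))
  invisible(x)
}
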