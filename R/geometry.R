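# Synthetic biventricular anatomy.
#
# The anatomy is an idealized two-ellipsoid ventricle pair discretized on a
# regular Cartesian grid (voxelization + Kuhn 6-tetrahedra split), the desk
# scale analogue of an image-derived tetrahedral mesh.  The LV is a full
# truncated ellipsoidal shell; the RV cavity is the part of a second,
# laterally shifted ellipsoid lying outside the LV epicardium, enclosed by a
# thin free wall.  The LV wall facing the RV cavity is labeled septum.
# Units: mm, ms, mm/ms.  Node and element indices are 1-based.

.kuhn_perms <- rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                     c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

# corner id (1..8) of a unit-cube offset: 1 + dx + 2 dy + 4 dz
.kuhn_corner_ids <- function() {
  t(apply(.kuhn_perms, 1, function(p) {
    bit <- c(1L, 2L, 4L)
    o1 <- bit[p[1]]
    o2 <- bit[p[1]] + bit[p[2]]
    c(1L, 1L + o1, 1L + o2, 8L)
  }))
}

.corner_offsets <- as.matrix(expand.grid(dx = 0:1, dy = 0:1, dz = 0:1))

#' @noRd
.ellipsoid_eval <- function(x, radii, center = c(0, 0, 0)) {
  sqrt(((x[, 1] - center[1]) / radii[1])^2 +
       ((x[, 2] - center[2]) / radii[2])^2 +
       ((x[, 3] - center[3]) / radii[3])^2)
}

.ellipsoid_grad <- function(x, radii, center = c(0, 0, 0)) {
  e <- pmax(.ellipsoid_eval(x, radii, center), 1e-12)
  cbind((x[, 1] - center[1]) / radii[1]^2,
        (x[, 2] - center[2]) / radii[2]^2,
        (x[, 3] - center[3]) / radii[3]^2) / e
}

.normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm < 1e-14] <- 1
  m / nrm
}

# Build nodes + tetrahedra from a set of grid cells (lower-corner integer
# coordinates).  All cells are split the same way, which makes the mesh
# conformal across shared faces.  Every tetrahedron has volume h^3/6.
.tetrahedralize_cells <- function(cells, origin, h) {
  m <- nrow(cells)
  # grid coordinates of the 8 corners of every cell
  corner_g <- vector("list", 8)
  for (ci in 1:8) {
    corner_g[[ci]] <- cbind(cells[, 1] + .corner_offsets[ci, 1],
                            cells[, 2] + .corner_offsets[ci, 2],
                            cells[, 3] + .corner_offsets[ci, 3])
  }
  allg <- do.call(rbind, corner_g)
  rng <- apply(allg, 2, range)
  dims <- rng[2, ] - rng[1, ] + 1L
  keyfun <- function(g) {
    (g[, 1] - rng[1, 1]) +
      (g[, 2] - rng[1, 2]) * dims[1] +
      (g[, 3] - rng[1, 3]) * (dims[1] * dims[2])
  }
  keys <- keyfun(allg)
  ukeys <- sort(unique(keys))
  node_id <- matrix(match(keys, ukeys), nrow = m)   # m x 8
  # recover node grid coords from keys
  k <- ukeys
  gz <- k %/% (dims[1] * dims[2])
  rem <- k %% (dims[1] * dims[2])
  gy <- rem %/% dims[1]
  gx <- rem %% dims[1]
  node_grid <- cbind(gx + rng[1, 1], gy + rng[1, 2], gz + rng[1, 3])
  nodes <- sweep(node_grid * h, 2, origin, "+")
  cid <- .kuhn_corner_ids()
  tets <- matrix(0L, nrow = 6 * m, ncol = 4)
  for (p in 1:6) {
    rows <- seq.int(p, by = 6L, length.out = m)
    tets[rows, ] <- cbind(node_id[, cid[p, 1]], node_id[, cid[p, 2]],
                          node_id[, cid[p, 3]], node_id[, cid[p, 4]])
  }
  cell_of_elem <- rep(seq_len(m), each = 6L)
  list(nodes = nodes, node_grid = node_grid, tets = tets,
       cell_of_elem = cell_of_elem, grid_range = rng, grid_dims = dims)
}

# largest face-connected component of a cell set
.largest_cell_component <- function(cells) {
  m <- nrow(cells)
  if (m == 0) return(integer(0))
  rng <- apply(cells, 2, range)
  dims <- rng[2, ] - rng[1, ] + 2L
  key <- (cells[, 1] - rng[1, 1]) + (cells[, 2] - rng[1, 2]) * dims[1] +
    (cells[, 3] - rng[1, 3]) * dims[1] * dims[2]
  ord <- order(key)
  skey <- key[ord]
  lookup <- function(k) {
    idx <- findInterval(k, skey)
    ok <- idx >= 1L & skey[pmax(idx, 1L)] == k
    out <- rep(NA_integer_, length(k))
    out[ok] <- ord[idx[ok]]
    out
  }
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  comp <- integer(m)
  cur <- 0L
  for (s in seq_len(m)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nxt <- integer(0)
      for (oi in 1:6) {
        nk <- (cells[frontier, 1] + offs[oi, 1] - rng[1, 1]) +
          (cells[frontier, 2] + offs[oi, 2] - rng[1, 2]) * dims[1] +
          (cells[frontier, 3] + offs[oi, 3] - rng[1, 3]) * dims[1] * dims[2]
        nb <- lookup(nk)
        nb <- nb[!is.na(nb)]
        nb <- nb[comp[nb] == 0L]
        if (length(nb)) {
          comp[nb] <- cur
          nxt <- c(nxt, nb)
        }
      }
      frontier <- unique(nxt)
    }
  }
  which(comp == which.max(tabulate(comp)))
}

.finish_mesh <- function(tt, h, origin, kind, geom,
                         wall_label, layer_label, aha_segment, depth) {
  m_elem <- nrow(tt$tets)
  mesh <- structure(list(
    nodes = tt$nodes, node_grid = tt$node_grid, tets = tt$tets,
    elem_volume = rep(h^3 / 6, m_elem),
    cell_of_elem = tt$cell_of_elem,
    wall_label = wall_label[tt$cell_of_elem],
    layer_label = layer_label[tt$cell_of_elem],
    aha_segment = aha_segment[tt$cell_of_elem],
    tissue_class = rep("normal", m_elem),
    depth = depth[tt$cell_of_elem],
    fiber = NULL,
    h = h, origin = origin, kind = kind, geom = geom,
    grid_range = tt$grid_range, grid_dims = tt$grid_dims,
    cache = new.env(parent = emptyenv())
  ), class = "ventricular_mesh")
  mesh$elem_center <- (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
                       mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
  mesh <- .assign_node_labels(mesh)
  mesh <- .assign_surfaces(mesh)
  mesh
}

.assign_node_labels <- function(mesh) {
  n <- nrow(mesh$nodes)
  idx <- as.vector(mesh$tets)
  elab <- rep(mesh$wall_label, 4)
  # majority label per node, ties resolved by fixed priority
  prio <- c(septum = 1L, LV_free = 2L, RV_free = 3L)
  lab <- factor(elab, levels = names(prio))
  counts <- matrix(0L, nrow = n, ncol = 3)
  for (li in 1:3) {
    sel <- as.integer(lab) == li
    tb <- tabulate(idx[sel], nbins = n)
    counts[, li] <- tb
  }
  mesh$node_wall <- names(prio)[max.col(counts, ties.method = "first")]
  eaha <- rep(mesh$aha_segment, 4)
  best <- rep(0L, n)
  first <- !duplicated(idx)
  # any incident LV element's segment (deterministic: first in element order)
  ord <- order(idx, rep(seq_len(nrow(mesh$tets)), 4))
  oidx <- idx[ord]; oaha <- eaha[ord]
  lv <- oaha > 0L
  f <- !duplicated(oidx[lv])
  best[oidx[lv][f]] <- oaha[lv][f]
  mesh$node_aha <- best
  mesh
}

.assign_surfaces <- function(mesh) {
  tets <- mesh$tets
  n <- nrow(mesh$nodes)
  faces <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 3, 4)],
                 tets[, c(1, 2, 4)], tets[, c(1, 2, 3)])
  owner <- rep(seq_len(nrow(tets)), times = 4)
  fs <- t(apply(faces, 1, sort.int))
  K <- n + 1
  fkey <- fs[, 1] + fs[, 2] * K + fs[, 3] * K * K
  dup <- fkey %in% fkey[duplicated(fkey)]
  bfaces <- faces[!dup, , drop = FALSE]
  bowner <- owner[!dup]
  cf <- (mesh$nodes[bfaces[, 1], , drop = FALSE] +
         mesh$nodes[bfaces[, 2], , drop = FALSE] +
         mesh$nodes[bfaces[, 3], , drop = FALSE]) / 3
  ct <- mesh$elem_center[bowner, , drop = FALSE]
  u <- .normalize_rows(cf - ct)
  p <- cf + 0.3 * mesh$h * u
  lab <- rep("epi", nrow(bfaces))
  if (mesh$kind == "biventricular") {
    g <- mesh$geom
    base <- p[, 3] > -1e-9
    lv_endo <- !base & .ellipsoid_eval(p, g$lv_inner) < 1
    rv_endo <- !base & !lv_endo & .ellipsoid_eval(p, g$rv_inner, g$rv_center) < 1 &
      .ellipsoid_eval(p, g$lv_outer) > 1
    lab[base] <- "base"
    lab[lv_endo] <- "endo_lv"
    lab[rv_endo] <- "endo_rv"
  }
  surf_nodes <- function(which_lab)
    sort(unique(as.vector(bfaces[lab == which_lab, , drop = FALSE])))
  mesh$surfaces <- list(endo_lv = surf_nodes("endo_lv"),
                        endo_rv = surf_nodes("endo_rv"),
                        epi = surf_nodes("epi"),
                        base = surf_nodes("base"))
  mesh$boundary_faces <- bfaces
  mesh$boundary_face_label <- lab
  mesh
}

#' Build an idealized biventricular tetrahedral mesh
#'
#' Generates a labeled two-cavity ventricular mesh standing in for an
#' image-derived patient anatomy: a full truncated-ellipsoid LV shell plus a
#' thin-walled RV crescent, voxelized at the requested edge length and split
#' into tetrahedra.  Elements carry wall labels (`LV_free`, `septum`,
#' `RV_free`), transmural layers (`endo`, `mid`, `epi` by depth thirds), AHA
#' 17-segment codes (LV only; 0 on the RV), tissue class and transmural depth.
#'
#' @param lv_inner_radii semi-axes (mm) of the LV endocardial ellipsoid
#'   (x, y, long axis z); the ventricle occupies z < 0, truncated at the base
#'   plane z = 0.  The default is a dilated, spherically remodeled LV
#'   (end-diastolic cavity volume about 190 ml), the phenotype of the CRT
#'   candidate population.
#' @param lv_wall LV wall thickness (mm); must resolve to >= 3 voxel layers
#'   for all three transmural layers to be populated.
#' @param rv_inner_radii,rv_center,rv_wall RV endocardial ellipsoid semi-axes,
#'   its center (shifted toward +x, the septal side), and RV free-wall
#'   thickness (mm).
#' @param edge_length voxel edge length (mm), default 4.
#' @param seed integer seed; the construction is deterministic, the seed is
#'   recorded for provenance.
#' @return an object of class `ventricular_mesh`.
#' @export
build_ventricles <- function(lv_inner_radii = c(42, 42, 52), lv_wall = 12,
                             rv_inner_radii = c(36, 30, 42),
                             rv_center = c(33, 0, -5), rv_wall = 5,
                             edge_length = 4, seed = 1L) {
  if (edge_length <= 0) stop("edge_length must be positive")
  if (lv_wall <= 0 || rv_wall <= 0) stop("wall thickness must be positive")
  if (any(lv_inner_radii <= 0) || any(rv_inner_radii <= 0))
    stop("ellipsoid radii must be positive")
  if (lv_wall >= min(lv_inner_radii)) stop("wall thickness must be smaller than radii")
  h <- edge_length
  geom <- list(lv_inner = lv_inner_radii, lv_outer = lv_inner_radii + lv_wall,
               rv_inner = rv_inner_radii, rv_outer = rv_inner_radii + rv_wall,
               rv_center = rv_center, seed = as.integer(seed))
  lo <- pmin(-geom$lv_outer, rv_center - geom$rv_outer)
  hi <- pmax(geom$lv_outer, rv_center + geom$rv_outer)
  hi[3] <- 0
  lo[3] <- min(-geom$lv_outer[3], rv_center[3] - geom$rv_outer[3])
  origin <- floor(lo / h) * h - h
  ncell <- ceiling((hi - origin) / h) + 1L
  grid <- as.matrix(expand.grid(i = 0:(ncell[1] - 1L), j = 0:(ncell[2] - 1L),
                                k = 0:(ncell[3] - 1L)))
  ctr <- sweep((grid + 0.5) * h, 2, origin, "+")
  below_base <- ctr[, 3] < 0
  e_lv_in <- .ellipsoid_eval(ctr, geom$lv_inner)
  e_lv_out <- .ellipsoid_eval(ctr, geom$lv_outer)
  e_rv_in <- .ellipsoid_eval(ctr, geom$rv_inner, rv_center)
  e_rv_out <- .ellipsoid_eval(ctr, geom$rv_outer, rv_center)
  in_lv <- below_base & e_lv_in >= 1 & e_lv_out <= 1
  in_rv <- below_base & !in_lv & e_rv_in >= 1 & e_rv_out <= 1 & e_lv_out > 1
  keep <- which(in_lv | in_rv)
  cells <- grid[keep, , drop = FALSE]
  comp <- .largest_cell_component(cells)
  keep <- keep[comp]
  cells <- grid[keep, , drop = FALSE]

  is_lv <- in_lv[keep]
  ctrk <- ctr[keep, , drop = FALSE]
  wall <- ifelse(is_lv, ifelse(e_rv_out[keep] <= 1, "septum", "LV_free"), "RV_free")
  fe <- ifelse(is_lv, e_lv_in[keep] - 1, e_rv_in[keep] - 1)
  fp <- ifelse(is_lv, 1 - e_lv_out[keep], 1 - e_rv_out[keep])
  depth <- pmin(pmax(fe / pmax(fe + fp, 1e-12), 0), 1)
  layer <- c("endo", "mid", "epi")[findInterval(depth, c(1 / 3, 2 / 3)) + 1L]
  aha <- .aha_segment(ctrk, geom, is_lv)

  tt <- .tetrahedralize_cells(cells, origin, h)
  .finish_mesh(tt, h, origin, "biventricular", geom, wall, layer, aha, depth)
}

# AHA 17-segment code from normalized apex-base level and circumferential
# angle; septum faces +x, anterior faces +y.  Basal/mid sectors are 60 deg,
# apical sectors 90 deg, apex cap below the endocardial apex level.
.aha_segment <- function(ctr, geom, is_lv) {
  seg <- integer(nrow(ctr))
  lv <- which(is_lv)
  if (!length(lv)) return(seg)
  level <- -ctr[lv, 3] / geom$lv_outer[3]
  phi <- (atan2(ctr[lv, 2], ctr[lv, 1]) * 180 / pi) %% 360
  basal_lookup <- function(deg) {
    c(2L, 1L, 6L, 5L, 4L, 3L)[findInterval(deg, c(60, 120, 180, 240, 300)) + 1L]
  }
  apical_lookup <- function(deg) {
    c(14L, 13L, 16L, 15L, 14L)[findInterval(deg, c(45, 135, 225, 315)) + 1L]
  }
  apex_level <- geom$lv_inner[3] / geom$lv_outer[3]
  s <- integer(length(lv))
  b <- level < 1 / 3
  m <- level >= 1 / 3 & level < 2 / 3
  a <- level >= 2 / 3 & level < apex_level
  x <- level >= apex_level
  s[b] <- basal_lookup(phi[b])
  s[m] <- basal_lookup(phi[m]) + 6L
  s[a] <- apical_lookup(phi[a])
  s[x] <- 17L
  seg[lv] <- s
  seg
}

#' Build a rectangular slab mesh
#'
#' A homogeneous tissue slab occupying `[0, lx] x [0, ly] x [0, lz]`,
#' voxelized at edge `h`.  Used for front-speed and convergence checks.
#' All elements are labeled `LV_free`/`mid`/`normal`; fibers default to the
#' +x direction (override with [set_uniform_fibers()]).
#'
#' @param lx,ly,lz slab dimensions, mm
#' @param h voxel edge length, mm
#' @return a `ventricular_mesh` of kind `"slab"`
#' @export
build_slab_mesh <- function(lx, ly, lz, h) {
  stopifnot(lx > 0, ly > 0, lz > 0, h > 0)
  nc <- c(round(lx / h), round(ly / h), round(lz / h))
  if (any(nc < 1)) stop("slab smaller than one voxel")
  cells <- as.matrix(expand.grid(i = 0:(nc[1] - 1L), j = 0:(nc[2] - 1L),
                                 k = 0:(nc[3] - 1L)))
  tt <- .tetrahedralize_cells(cells, c(0, 0, 0), h)
  mcell <- nrow(cells)
  mesh <- .finish_mesh(tt, h, c(0, 0, 0), "slab", NULL,
                       rep("LV_free", mcell), rep("mid", mcell),
                       rep(0L, mcell), rep(0.5, mcell))
  set_uniform_fibers(mesh, c(1, 0, 0))
}

#' Set a uniform fiber direction on every element
#' @param mesh a `ventricular_mesh`
#' @param dir direction vector (normalized internally)
#' @return the mesh with its `fiber` field set
#' @export
set_uniform_fibers <- function(mesh, dir) {
  d <- dir / sqrt(sum(dir^2))
  mesh$fiber <- matrix(d, nrow = nrow(mesh$tets), ncol = 3, byrow = TRUE)
  mesh$cache <- new.env(parent = emptyenv())
  mesh
}

#' Assign a rule-based transmural fiber field
#'
#' The fiber helix angle interpolates linearly from `alpha_endo` at the
#' endocardium to `alpha_epi` at the epicardium across the normalized
#' transmural depth, the simplest member of the rule-based family used for
#' ventricular fiber architecture.  Fibers are tangent to the local wall
#' surface (orthogonal to the transmural direction) and unit norm.
#'
#' @param mesh a biventricular `ventricular_mesh`
#' @param alpha_endo,alpha_epi helix angles in degrees (defaults +60 / -60)
#' @return the mesh with a per-element `fiber` matrix
#' @export
assign_fibers <- function(mesh, alpha_endo = 60, alpha_epi = -60) {
  if (mesh$kind != "biventricular")
    stop("rule-based fibers need the biventricular geometry; use set_uniform_fibers() for slabs")
  g <- mesh$geom
  x <- mesh$elem_center
  lv <- mesh$wall_label != "RV_free"
  n_in <- .ellipsoid_grad(x, g$lv_inner)
  n_out <- .ellipsoid_grad(x, g$lv_outer)
  n_in_rv <- .ellipsoid_grad(x, g$rv_inner, g$rv_center)
  n_out_rv <- .ellipsoid_grad(x, g$rv_outer, g$rv_center)
  nrm <- n_in + n_out
  nrm[!lv, ] <- n_in_rv[!lv, ] + n_out_rv[!lv, ]
  nrm <- .normalize_rows(nrm)
  zhat <- c(0, 0, 1)
  circ <- cbind(-nrm[, 2], nrm[, 1], 0)       # zhat x n
  bad <- sqrt(rowSums(circ^2)) < 1e-8
  if (any(bad)) circ[bad, ] <- cbind(1, 0, 0)[rep(1, sum(bad)), , drop = FALSE]
  circ <- .normalize_rows(circ)
  long <- cbind(nrm[, 2] * circ[, 3] - nrm[, 3] * circ[, 2],
                nrm[, 3] * circ[, 1] - nrm[, 1] * circ[, 3],
                nrm[, 1] * circ[, 2] - nrm[, 2] * circ[, 1])
  depth <- mesh$depth
  depth[!is.finite(depth)] <- 0.5
  alpha <- (alpha_endo + depth * (alpha_epi - alpha_endo)) * pi / 180
  fib <- circ * cos(alpha) + long * sin(alpha)
  mesh$fiber <- .normalize_rows(fib)
  mesh$cache <- new.env(parent = emptyenv())
  mesh
}

#' Define a lesion map on the AHA (segment, layer) grid
#'
#' @param segment integer vector of AHA segments (1-17)
#' @param layer character vector, one of `"endo"`, `"mid"`, `"epi"` (recycled)
#' @param class `"fibrosis"` or `"scar"` (recycled)
#' @return a `lesion_spec` data frame
#' @export
lesion_spec <- function(segment = integer(0), layer = character(0),
                        class = character(0)) {
  spec <- data.frame(segment = as.integer(segment), layer = layer,
                     class = class, stringsAsFactors = FALSE)
  if (nrow(spec)) {
    if (any(spec$segment < 1L | spec$segment > 17L))
      stop("lesion segments must be AHA codes 1-17 (LV only)")
    if (!all(spec$layer %in% c("endo", "mid", "epi")))
      stop("lesion layer must be endo, mid or epi")
    if (!all(spec$class %in% c("fibrosis", "scar")))
      stop("lesion class must be fibrosis or scar")
  }
  class(spec) <- c("lesion_spec", class(spec))
  spec
}

#' Apply a schematic (segment, layer) lesion map to the mesh
#'
#' Scar elements become non-excitable (excluded from propagation and from the
#' myocardial tissue volume); fibrosis elements conduct at the fibrosis
#' conductivity fraction of the conduction model.  Lesions are LV-only, at
#' the same (AHA segment, transmural layer) granularity as an expert MRI
#' damage annotation.
#'
#' @param mesh a `ventricular_mesh` with AHA labels
#' @param spec a [lesion_spec()]
#' @return the mesh with `tissue_class` updated; the element counts set per
#'   class are available as `attr(mesh, "lesion_counts")`
#' @export
apply_lesions <- function(mesh, spec) {
  if (!inherits(spec, "lesion_spec")) spec <- do.call(lesion_spec, as.list(spec))
  mesh$tissue_class <- rep("normal", length(mesh$tissue_class))
  counts <- c(fibrosis = 0L, scar = 0L)
  if (nrow(spec)) {
    for (r in seq_len(nrow(spec))) {
      hit <- mesh$aha_segment == spec$segment[r] & mesh$layer_label == spec$layer[r]
      mesh$tissue_class[hit] <- spec$class[r]
    }
    counts["fibrosis"] <- sum(mesh$tissue_class == "fibrosis")
    counts["scar"] <- sum(mesh$tissue_class == "scar")
  }
  attr(mesh, "lesion_counts") <- counts
  mesh$cache <- new.env(parent = emptyenv())
  mesh
}

#' Place RV and LV pacing sites
#'
#' The RV site is the most apical RV endocardial node (minimal long-axis
#' coordinate), mimicking an apical RV lead.  The LV site is an epicardial
#' free-wall node closest to a target circumferential angle and apex-base
#' level, emulating a coronary-sinus-accessible (posterolateral by default)
#' LV lead position.  If the requested position lands on scar the nearest
#' non-scar node is substituted with a warning.
#'
#' @param mesh a biventricular `ventricular_mesh`
#' @param lv_angle_deg target circumferential angle for the LV site, degrees
#'   (septum at 0, anterior at 90; default 210 = inferolateral)
#' @param lv_level target apex-base level in (0, 1), default 0.5 (mid)
#' @param rv_lv_delay inter-lead stimulation delay, ms (default 0)
#' @param seed recorded for provenance; placement itself is deterministic
#' @return a `pacing_config` list with `mode`, `rv_site`, `lv_site`,
#'   `rv_lv_delay`
#' @export
place_pacing_sites <- function(mesh, lv_angle_deg = 210, lv_level = 0.5,
                               rv_lv_delay = 0, seed = 1L) {
  if (mesh$kind != "biventricular") stop("pacing sites need the biventricular geometry")
  rv_nodes <- mesh$surfaces$endo_rv
  if (!length(rv_nodes)) stop("RV endocardial surface is empty")
  rv_site <- rv_nodes[which.min(mesh$nodes[rv_nodes, 3])]

  epi_nodes <- mesh$surfaces$epi
  lvfree <- epi_nodes[mesh$node_wall[epi_nodes] == "LV_free"]
  if (!length(lvfree)) stop("no LV free-wall epicardial nodes")
  xy <- mesh$nodes[lvfree, , drop = FALSE]
  phi <- (atan2(xy[, 2], xy[, 1]) * 180 / pi) %% 360
  dphi <- pmin(abs(phi - lv_angle_deg %% 360), 360 - abs(phi - lv_angle_deg %% 360))
  z_target <- -lv_level * mesh$geom$lv_outer[3]
  rad <- mean(mesh$geom$lv_outer[1:2])
  score <- (dphi * pi / 180 * rad)^2 + (xy[, 3] - z_target)^2
  ord <- order(score, lvfree)
  node_scar <- .node_on_scar(mesh)
  pick <- lvfree[ord]
  lv_site <- pick[1]
  if (node_scar[lv_site]) {
    ok <- pick[!node_scar[pick]]
    if (!length(ok)) stop("all candidate LV sites lie on scar")
    lv_site <- ok[1]
    warning("requested LV pacing position lies on scar; nearest non-scar node substituted")
  }
  structure(list(mode = "BiV", rv_site = rv_site, lv_site = lv_site,
                 rv_lv_delay = rv_lv_delay, seed = as.integer(seed)),
            class = "pacing_config")
}

# TRUE for nodes all of whose incident elements are scar
.node_on_scar <- function(mesh) {
  n <- nrow(mesh$nodes)
  idx <- as.vector(mesh$tets)
  nonscar <- rep(mesh$tissue_class != "scar", 4)
  has_ok <- tabulate(idx[nonscar], nbins = n) > 0
  incident <- tabulate(idx, nbins = n) > 0
  incident & !has_ok
}

#' Synthetic torso electrode positions
#'
#' Nine physical electrode landmarks (RA, LA, LL limb electrodes and
#' precordial V1-V6) at fixed synthetic positions on a virtual torso around
#' the heart (heart base at the origin, anterior chest toward +y, patient
#' right toward +x).  Positions are stand-ins: the source study located
#' electrodes on each patient's imaged torso.
#'
#' @return a `torso_model` list with `electrodes`, a 9 x 3 matrix (mm) with
#'   rownames RA, LA, LL, V1..V6
#' @export
torso_electrodes <- function() {
  el <- rbind(RA = c(120, 40, 220), LA = c(-120, 40, 220), LL = c(-80, 20, -500),
              V1 = c(40, 85, -5), V2 = c(15, 92, -8), V3 = c(-8, 94, -22),
              V4 = c(-28, 90, -36), V5 = c(-48, 78, -42), V6 = c(-64, 58, -46))
  colnames(el) <- c("x", "y", "z")
  structure(list(electrodes = el), class = "torso_model")
}

#' Total element volume by predicate, mm^3
#' @noRd
.volume_where <- function(mesh, sel) sum(mesh$elem_volume[sel])

#' @export
print.ventricular_mesh <- function(x, ...) {
  cat(sprintf("ventricular_mesh (%s): %d nodes, %d tetrahedra, h = %g mm\n",
              x$kind, nrow(x$nodes), nrow(x$tets), x$h))
  cat(sprintf("  walls: %s\n", paste(sprintf("%s=%d", names(table(x$wall_label)),
                                             as.integer(table(x$wall_label))), collapse = ", ")))
  cat(sprintf("  tissue: %s\n", paste(sprintf("%s=%d", names(table(x$tissue_class)),
                                              as.integer(table(x$tissue_class))), collapse = ", ")))
  invisible(x)
}
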