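# Legacy-ASCII VTK unstructured-grid export/import.
#
# Meshes travel as VTK unstructured grids (cell type 10 = tetrahedron) with
# the label fields as named CELL_DATA arrays and activation maps as named
# POINT_DATA arrays.  The legacy ASCII dialect is written and parsed
# directly; files are interoperable with standard VTK viewers.

.vtk_label_codes <- list(
  wall_label = c(LV_free = 1L, septum = 2L, RV_free = 3L),
  layer_label = c(endo = 1L, mid = 2L, epi = 3L),
  tissue_class = c(normal = 0L, fibrosis = 1L, scar = 2L)
)

#' Write a mesh (and optional node fields) as a legacy VTK unstructured grid
#'
#' Cell data: `wall_label`, `layer_label`, `tissue_class` (integer-coded),
#' `aha_segment`, and the `fiber` vector field when present.  Extra per-node
#' scalar fields (e.g. activation times) can be passed via `point_data`.
#'
#' @param mesh a `ventricular_mesh`
#' @param path output file path
#' @param point_data named list of per-node numeric vectors
#' @return `path`, invisibly
#' @export
write_vtk_mesh <- function(mesh, path, point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  wl("# vtk DataFile Version 3.0")
  wl("crtsim ventricular mesh")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS %d double", n)
  writeLines(apply(format(mesh$nodes, trim = TRUE, digits = 10), 1, paste,
                   collapse = " "), con)
  wl("CELLS %d %d", m, 5L * m)
  writeLines(paste(4L, mesh$tets[, 1] - 1L, mesh$tets[, 2] - 1L,
                   mesh$tets[, 3] - 1L, mesh$tets[, 4] - 1L), con)
  wl("CELL_TYPES %d", m)
  writeLines(as.character(rep(10L, m)), con)
  wl("CELL_DATA %d", m)
  for (fld in names(.vtk_label_codes)) {
    codes <- .vtk_label_codes[[fld]]
    wl("SCALARS %s int 1", fld)
    wl("LOOKUP_TABLE default")
    writeLines(as.character(codes[mesh[[fld]]]), con)
  }
  wl("SCALARS aha_segment int 1")
  wl("LOOKUP_TABLE default")
  writeLines(as.character(mesh$aha_segment), con)
  if (!is.null(mesh$fiber)) {
    wl("VECTORS fiber double")
    writeLines(apply(format(mesh$fiber, trim = TRUE, digits = 10), 1, paste,
                     collapse = " "), con)
  }
  if (length(point_data)) {
    wl("POINT_DATA %d", n)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (length(v) != n) stop("point_data field '", nm, "' has wrong length")
      wl("SCALARS %s double 1", nm)
      wl("LOOKUP_TABLE default")
      writeLines(format(v, trim = TRUE, digits = 10), con)
    }
  }
  invisible(path)
}

#' Read a legacy VTK unstructured grid written by [write_vtk_mesh()]
#'
#' @param path file path
#' @return list with `nodes`, `tets` (1-based), decoded label vectors,
#'   `aha_segment`, `fiber` (or NULL) and any `point_data` scalar fields
#' @export
read_vtk_mesh <- function(path) {
  lines <- readLines(path)
  find <- function(pat) grep(pat, lines)[1]
  ip <- find("^POINTS")
  n <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  nodes <- matrix(scan(text = lines[(ip + 1):(ip + n)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  ic <- find("^CELLS")
  m <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cellrows <- matrix(scan(text = lines[(ic + 1):(ic + m)], quiet = TRUE),
                     ncol = 5, byrow = TRUE)
  tets <- cellrows[, 2:5, drop = FALSE] + 1L
  out <- list(nodes = nodes, tets = tets, fiber = NULL, point_data = list())
  read_scalar_after <- function(i, len, what = double()) {
    scan(text = lines[(i + 2):(i + 1 + len)], what = what, quiet = TRUE)
  }
  icd <- find("^CELL_DATA")
  ipd <- find("^POINT_DATA")
  for (i in grep("^SCALARS|^VECTORS", lines)) {
    parts <- strsplit(lines[i], "\\s+")[[1]]
    nm <- parts[2]
    in_cell <- !is.na(icd) && i > icd && (is.na(ipd) || i < ipd)
    len <- if (in_cell) m else n
    if (parts[1] == "VECTORS") {
      out$fiber <- matrix(scan(text = lines[(i + 1):(i + len)], quiet = TRUE),
                          ncol = 3, byrow = TRUE)
    } else if (nm %in% names(.vtk_label_codes)) {
      codes <- .vtk_label_codes[[nm]]
      v <- read_scalar_after(i, len)
      out[[nm]] <- names(codes)[match(v, codes)]
    } else if (in_cell) {
      out[[nm]] <- as.integer(read_scalar_after(i, len))
    } else {
      out$point_data[[nm]] <- read_scalar_after(i, len)
    }
  }
  out
}

#' Write an activation map as node data on the mesh
#'
#' Infinite (scar-isolated) activation times are written as -1.
#'
#' @param map an `activation_map`
#' @param mesh the mesh
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vtk_activation <- function(map, mesh, path) {
  at <- map$at
  at[!is.finite(at)] <- -1
  write_vtk_mesh(mesh, path, point_data = list(activation_time = at))
}
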