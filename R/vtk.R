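## Legacy ASCII VTK output for meshes, surfaces and field snapshots, for
## inspection in ParaView-style viewers.

#' Write a mesh (with optional fields) as legacy ASCII VTK
#'
#' @param mesh an `lv_mesh` (2D nodes are padded with z = 0).
#' @param path output `.vtk` file.
#' @param point_data named list of nodal fields: numeric vectors (scalars)
#'   or n x d matrices (vectors, padded to 3 components).
#' @param cell_data named list of per-element fields in canonical element
#'   order (tri, quad, tet).
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes)
  xyz <- mesh$nodes
  if (ncol(xyz) == 2) xyz <- cbind(xyz, 0)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("lvflow mesh")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d double", n)
  writeLines(sprintf("%.10g %.10g %.10g", xyz[, 1], xyz[, 2], xyz[, 3]), con)
  els <- list(list(m = mesh$tri, t = 5L), list(m = mesh$quad, t = 9L),
              list(m = mesh$tet, t = 10L))
  ncell <- sum(vapply(els, function(e) nrow(e$m), 1L))
  tot <- sum(vapply(els, function(e) nrow(e$m) * (ncol(e$m) + 1L), 1L))
  w("CELLS %d %d", ncell, tot)
  for (e in els) if (nrow(e$m)) {
    k <- ncol(e$m)
    writeLines(paste(k, apply(e$m - 1L, 1, paste, collapse = " ")), con)
  }
  w("CELL_TYPES %d", ncell)
  for (e in els) if (nrow(e$m)) writeLines(as.character(rep(e$t, nrow(e$m))), con)
  if (length(point_data)) {
    w("POINT_DATA %d", n)
    for (nm in names(point_data)) .vtk_field(con, nm, point_data[[nm]])
  }
  if (length(cell_data)) {
    w("CELL_DATA %d", ncell)
    for (nm in names(cell_data)) .vtk_field(con, nm, cell_data[[nm]])
  }
  invisible(path)
}

.vtk_field <- function(con, name, val) {
  if (is.matrix(val)) {
    v <- val
    if (ncol(v) == 2) v <- cbind(v, 0)
    writeLines(sprintf("VECTORS %s double", name), con)
    writeLines(sprintf("%.10g %.10g %.10g", v[, 1], v[, 2], v[, 3]), con)
  } else {
    writeLines(sprintf("SCALARS %s double 1", name), con)
    writeLines("LOOKUP_TABLE default", con)
    writeLines(sprintf("%.10g", val), con)
  }
}

#' Write a triangulated surface as legacy ASCII VTK polydata
#'
#' @param nodes n x 3 coordinates.
#' @param tris m x 3 triangle node indices (1-based).
#' @param path output file.
#' @param point_data named list of nodal fields (see [write_vtk_mesh()]).
#' @return `path`, invisibly.
#' @export
write_vtk_surface <- function(nodes, tris, path, point_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("lvflow surface")
  w("ASCII")
  w("DATASET POLYDATA")
  w("POINTS %d double", nrow(nodes))
  writeLines(sprintf("%.10g %.10g %.10g", nodes[, 1], nodes[, 2], nodes[, 3]), con)
  w("POLYGONS %d %d", nrow(tris), 4L * nrow(tris))
  writeLines(paste(3L, apply(tris - 1L, 1, paste, collapse = " ")), con)
  if (length(point_data)) {
    w("POINT_DATA %d", nrow(nodes))
    for (nm in names(point_data)) .vtk_field(con, nm, point_data[[nm]])
  }
  invisible(path)
}

#' Write a flow-state snapshot (velocity, pressure, KE) as VTK
#'
#' @param state `lv_flow_state`.
#' @param path output file.
#' @param props [fluid_props()] for the KE field.
#' @return `path`, invisibly.
#' @export
write_vtk_state <- function(state, path, props = fluid_props()) {
  write_vtk_mesh(state$mesh, path,
                 point_data = list(velocity = state$v, pressure = state$p,
                                   ke = ke_density(state, props),
                                   mesh_velocity = state$w))
}
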