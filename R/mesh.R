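## Finite-element meshes for the lumen.
##
## An "lv_mesh" is a list:
##   dim      2 or 3
##   nodes    n x dim coordinate matrix (mm unless attr(unit) says otherwise)
##   tri      m3 x 3 integer matrix (2D linear triangles), may have 0 rows
##   quad     m4 x 4 integer matrix (2D bilinear quadrilaterals), 2D only
##   tet      m4 x 4 integer matrix (3D linear tetrahedra), 3D only
##   bfaces   boundary faces: 2 columns (edges) in 2D, 3 columns in 3D
##   btag     character tag per boundary face ("wall", "io", ...)
##   unit     "mm" or "m"

new_mesh <- function(dim, nodes, tri = NULL, quad = NULL, tet = NULL,
                     bfaces = NULL, btag = NULL, unit = "mm") {
  m <- list(dim = dim, nodes = nodes,
            tri = tri %||% matrix(integer(), 0, 3),
            quad = quad %||% matrix(integer(), 0, 4),
            tet = tet %||% matrix(integer(), 0, 4),
            bfaces = bfaces, btag = btag, unit = unit)
  class(m) <- "lv_mesh"
  m
}

#' @export
print.lv_mesh <- function(x, ...) {
  cat(sprintf("<lv_mesh> %dD, %d nodes, %d tri, %d quad, %d tet [%s]\n",
              x$dim, nrow(x$nodes), nrow(x$tri), nrow(x$quad), nrow(x$tet), x$unit))
  if (!is.null(x$btag)) {
    tb <- table(x$btag)
    cat("  boundary faces:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

n_elements <- function(mesh) nrow(mesh$tri) + nrow(mesh$quad) + nrow(mesh$tet)

mesh_in_meters <- function(mesh) {
  if (mesh$unit == "m") return(mesh)
  mesh$nodes <- mesh$nodes * 1e-3
  mesh$unit <- "m"
  mesh
}

#' Node indices of tagged boundary faces
#'
#' @param mesh an `lv_mesh`.
#' @param tag boundary tag(s), e.g. "wall" or "io".
#' @return sorted unique node indices lying on the tagged boundary.
#' @export
boundary_nodes <- function(mesh, tag) {
  sort(unique(as.integer(mesh$bfaces[mesh$btag %in% tag, , drop = FALSE])))
}

## ---- boundary extraction -------------------------------------------------

## Faces that appear exactly once across all elements are boundary faces.
extract_boundary <- function(mesh) {
  if (mesh$dim == 2) {
    e <- rbind(
      if (nrow(mesh$tri)) do.call(rbind, lapply(list(c(1, 2), c(2, 3), c(3, 1)),
        function(p) mesh$tri[, p, drop = FALSE])),
      if (nrow(mesh$quad)) do.call(rbind, lapply(list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)),
        function(p) mesh$quad[, p, drop = FALSE])))
  } else {
    e <- do.call(rbind, lapply(list(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(3, 1, 4)),
      function(p) mesh$tet[, p, drop = FALSE]))
  }
  key <- apply(t(apply(e, 1, sort)), 1, paste, collapse = "_")
  once <- names(which(table(key) == 1))
  e[key %in% once, , drop = FALSE]
}

## ---- structured 2D rectangle (quads) -------------------------------------

#' Structured quadrilateral mesh of an axis-aligned rectangle
#'
#' @param x0,x1,y0,y1 rectangle extents (mm).
#' @param nx,ny number of cells per direction.
#' @param io which side carries the open (zero-traction) boundary:
#'   one of "top", "bottom", "left", "right", or "none".
#' @param tags optional named list overriding the tag of each side
#'   (names among top/bottom/left/right), e.g. `list(left = "inflow")`.
#' @return an `lv_mesh`.
#' @export
mesh_rect2d <- function(x0, x1, y0, y1, nx, ny, io = "top", tags = list()) {
  xs <- seq(x0, x1, length.out = nx + 1)
  ys <- seq(y0, y1, length.out = ny + 1)
  nodes <- cbind(rep(xs, times = ny + 1), rep(ys, each = nx + 1))
  id <- function(i, j) (j - 1L) * (nx + 1L) + i          # i along x, j along y
  i <- rep(seq_len(nx), times = ny); j <- rep(seq_len(ny), each = nx)
  quad <- cbind(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L))
  side_tag <- function(side) tags[[side]] %||% (if (identical(io, side)) "io" else "wall")
  bf <- rbind(
    cbind(id(seq_len(nx), 1L), id(seq_len(nx) + 1L, 1L)),                    # bottom
    cbind(id(seq_len(nx) + 1L, ny + 1L), id(seq_len(nx), ny + 1L)),          # top
    cbind(id(1L, seq_len(ny) + 1L), id(1L, seq_len(ny))),                    # left
    cbind(id(nx + 1L, seq_len(ny)), id(nx + 1L, seq_len(ny) + 1L)))          # right
  bt <- c(rep(side_tag("bottom"), nx), rep(side_tag("top"), nx),
          rep(side_tag("left"), ny), rep(side_tag("right"), ny))
  new_mesh(2, nodes, quad = quad, bfaces = bf, btag = bt)
}

## ---- 2D lumen mesh by transfinite blending -------------------------------

#' Mesh a 2D lumen bounded by a wall polyline and a straight IO segment
#'
#' The wall runs from the left IO endpoint, around the lumen (below the IO
#' line), back to the right IO endpoint; the IO segment closes the domain on
#' the chord between the endpoints. Nodes are laid out by linear transfinite
#' blending between the IO chord and the wall, so the wall boundary nodes of
#' the mesh coincide exactly with the supplied wall points (this is what lets
#' the motion law drive the mesh directly). Cells are quadrilaterals except
#' for the collapsed end columns, which degenerate to triangles
#' (quad-dominant, as appropriate for this family of domains).
#'
#' @param wall (n+1) x 2 matrix, open polyline from the first to the last IO
#'   endpoint; both endpoints must lie on the IO line.
#' @param n_layers number of element layers between IO chord and wall.
#' @return an `lv_mesh` with boundary tags "wall" and "io", plus attribute
#'   `wall_index` mapping wall polyline points to mesh node ids.
#' @export
mesh_lumen2d <- function(wall, n_layers = 8) {
  wall <- as.matrix(wall)
  n_xi <- nrow(wall) - 1L
  if (n_xi < 3) stopf("wall polyline needs at least 4 points")
  p0 <- wall[1, ]; p1 <- wall[nrow(wall), ]
  ## chord parameter follows the wall's normalized arclength so columns stay
  ## roughly orthogonal
  s <- c(0, cumsum(sqrt(rowSums(diff(wall)^2))))
  xi <- s / s[length(s)]
  eta <- seq(0, 1, length.out = n_layers + 1)
  top <- cbind(p0[1] + xi * (p1[1] - p0[1]), p0[2] + xi * (p1[2] - p0[2]))
  ## node grid: column i (1..n_xi+1), layer j (1 = IO chord, n_layers+1 = wall)
  nid <- matrix(0L, n_xi + 1L, n_layers + 1L)
  nodes <- matrix(0, 0, 2)
  for (i in seq_len(n_xi + 1L)) {
    if (i == 1L || i == n_xi + 1L) {
      nodes <- rbind(nodes, wall[i, ])          # collapsed column: single node
      nid[i, ] <- nrow(nodes)
    } else {
      for (j in seq_len(n_layers + 1L)) {
        e <- eta[j]
        nodes <- rbind(nodes, (1 - e) * top[i, ] + e * wall[i, ])
        nid[i, j] <- nrow(nodes)
      }
    }
  }
  quad <- matrix(integer(), 0, 4); tri <- matrix(integer(), 0, 3)
  for (i in seq_len(n_xi)) for (j in seq_len(n_layers)) {
    v <- c(nid[i, j], nid[i + 1L, j], nid[i + 1L, j + 1L], nid[i, j + 1L])
    u <- unique(v)
    if (length(u) == 4L) quad <- rbind(quad, v)
    else if (length(u) == 3L) tri <- rbind(tri, u)
  }
  ## enforce positive orientation
  orient2 <- function(el) {
    a <- el[, 1]; b <- el[, 2]; cc <- el[, 3]
    s2 <- (nodes[b, 1] - nodes[a, 1]) * (nodes[cc, 2] - nodes[a, 2]) -
          (nodes[b, 2] - nodes[a, 2]) * (nodes[cc, 1] - nodes[a, 1])
    s2
  }
  if (nrow(tri)) {
    flip <- orient2(tri) < 0
    tri[flip, ] <- tri[flip, c(1, 3, 2), drop = FALSE]
  }
  if (nrow(quad)) {
    flip <- orient2(quad[, 1:3, drop = FALSE]) < 0
    quad[flip, ] <- quad[flip, c(4, 3, 2, 1), drop = FALSE]
  }
  wall_index <- nid[, n_layers + 1L]
  io_index <- nid[, 1L]
  bf <- rbind(cbind(wall_index[-length(wall_index)], wall_index[-1]),
              cbind(io_index[-length(io_index)], io_index[-1]))
  bt <- c(rep("wall", n_xi), rep("io", n_xi))
  ## drop zero-length io faces at the collapsed corners
  keep <- bf[, 1] != bf[, 2]
  m <- new_mesh(2, nodes, tri = tri, quad = quad,
                bfaces = bf[keep, , drop = FALSE], btag = bt[keep])
  attr(m, "wall_index") <- wall_index
  attr(m, "io_index") <- io_index
  q <- mesh_quality(m)
  if (q$min_jacobian <= 0) stopf("2D lumen meshing produced inverted cells (min J = %g)", q$min_jacobian)
  attr(m, "quality") <- q
  m
}

## ---- 3D lumen mesh from stacked rings ------------------------------------

## Consistent prism -> 3 tets split (diagonals through the minimal global
## vertex id on each quad face), so adjacent prisms share triangulated faces.
split_prism <- function(v) {
  ## v: 6 global ids, bottom (1,2,3) and top (4,5,6) with 4 above 1 etc.
  k <- which.min(v)
  rot <- switch(k, c(1,2,3,4,5,6), c(2,3,1,5,6,4), c(3,1,2,6,4,5),
                   c(4,6,5,1,3,2), c(5,4,6,2,1,3), c(6,5,4,3,2,1))
  w <- v[rot]
  if (min(w[2], w[6]) < min(w[3], w[5]))
    rbind(w[c(1,2,3,6)], w[c(1,2,6,5)], w[c(1,5,6,4)])
  else
    rbind(w[c(1,2,3,5)], w[c(1,5,3,6)], w[c(1,5,6,4)])
}

#' Tetrahedral mesh of a lumen described by stacked cross-section rings
#'
#' Builds a structured, axis-centred tetrahedral mesh: every ring level gets a
#' disk of nodes (level centroid plus `n_radial` concentric layers scaled
#' toward the ring), disks on consecutive levels are joined by prisms split
#' consistently into tetrahedra, and the apex is closed by a tetrahedral fan.
#' Identical ring counts at every phase give identical connectivity, so the
#' same mesh carries the whole cycle via nodal displacements.
#'
#' @param rings array L x n_theta x 3 of ring coordinates (mm), level 1 = base
#'   (IO plane), ordered base to apex.
#' @param apex length-3 apex point, or NULL for a flat-capped lumen (the last
#'   ring's disk becomes the bottom wall, as for a cylinder).
#' @param n_radial number of radial node layers between axis and wall.
#' @return `lv_mesh` with tags "wall"/"io"; attributes `ring_index`
#'   (L x n_theta matrix of node ids of the ring/wall nodes), `apex_index`
#'   (NA for flat caps), `bottom_disk` (node ids of the bottom disk when
#'   flat-capped), and `quality`.
#' @export
mesh_lumen3d <- function(rings, apex = NULL, n_radial = 4) {
  dims <- dim(rings)
  L <- dims[1]; nt <- dims[2]
  if (L < 2) stopf("need at least 2 ring levels")
  if (nt < 8) stopf("need at least 8 points per ring")
  nodes <- matrix(0, 0, 3)
  ## disk node ids: did[[l]] is (n_radial+1) x nt; row 1 is the axis node
  ## replicated, row r the (r-1)-th layer; row n_radial+1 the ring itself.
  did <- vector("list", L)
  for (l in seq_len(L)) {
    ring <- rings[l, , ]
    cen <- colMeans(ring)
    nodes <- rbind(nodes, cen)
    axis_id <- nrow(nodes)
    ids <- matrix(0L, n_radial + 1L, nt)
    ids[1, ] <- axis_id
    for (r in seq_len(n_radial)) {
      f <- r / n_radial
      layer <- sweep(ring, 2, cen, "-") * f
      layer <- sweep(layer, 2, cen, "+")
      nodes <- rbind(nodes, layer)
      ids[r + 1L, ] <- nrow(nodes) - nt + seq_len(nt)
    }
    did[[l]] <- ids
  }
  if (!is.null(apex)) {
    nodes <- rbind(nodes, apex)
    apex_id <- nrow(nodes)
  } else apex_id <- NA_integer_

  ## disk template triangles in (layer, theta) index space, same every level
  disk_tris <- function(ids) {
    tri <- matrix(integer(), 0, 3)
    jn <- c(seq_len(nt)[-1], 1L)
    ## inner fan
    tri <- rbind(tri, cbind(ids[1, 1], ids[2, seq_len(nt)], ids[2, jn]))
    if (n_radial >= 2) for (r in 2:n_radial) {
      a <- ids[r, seq_len(nt)]; b <- ids[r, jn]
      A <- ids[r + 1L, seq_len(nt)]; B <- ids[r + 1L, jn]
      ## split quads (a,b,B,A) by diagonal through the min id
      d1 <- pmin(a, B) < pmin(b, A)
      tri <- rbind(tri,
                   cbind(a, b, B)[d1, , drop = FALSE], cbind(a, B, A)[d1, , drop = FALSE],
                   cbind(a, b, A)[!d1, , drop = FALSE], cbind(b, B, A)[!d1, , drop = FALSE])
    }
    tri
  }
  tmpl <- disk_tris(did[[1]])      # ids of level 1; use index mapping for others
  ## map level-1 ids to per-level ids via position lookup
  pos <- match(as.vector(tmpl), as.vector(did[[1]]))
  acc <- vector("list", L)
  for (l in seq_len(L - 1L)) {
    bot <- matrix(as.vector(did[[l]])[pos], ncol = 3)
    top <- matrix(as.vector(did[[l + 1L]])[pos], ncol = 3)
    part <- vector("list", nrow(bot))
    for (e in seq_len(nrow(bot))) {
      v <- c(bot[e, ], top[e, ])
      if (length(unique(v)) == 6L) part[[e]] <- split_prism(v)
    }
    acc[[l]] <- do.call(rbind, part)
  }
  ## apex cap (skipped for flat-capped lumina)
  if (!is.na(apex_id)) {
    capb <- matrix(as.vector(did[[L]])[pos], ncol = 3)
    acc[[L]] <- cbind(capb, apex_id)
  }
  tet <- do.call(rbind, acc)

  vol <- tet_volumes(nodes, tet)
  flip <- vol < 0
  tet[flip, ] <- tet[flip, c(1, 3, 2, 4), drop = FALSE]
  m <- new_mesh(3, nodes, tet = tet)
  bf <- extract_boundary(m)
  zb <- nodes[did[[1]][1, 1], 3]
  ztol <- 1e-6 * max(1, diff(range(nodes[, 3])))
  on_base <- matrix(abs(nodes[bf, 3] - zb) < ztol, nrow = nrow(bf))
  bt <- ifelse(rowSums(on_base) == 3L, "io", "wall")
  m$bfaces <- bf; m$btag <- bt
  attr(m, "ring_index") <- do.call(rbind, lapply(did, function(x) x[n_radial + 1L, ]))
  attr(m, "apex_index") <- apex_id
  if (is.na(apex_id)) attr(m, "bottom_disk") <- did[[L]]
  q <- mesh_quality(m)
  if (q$min_jacobian <= 0) stopf("3D lumen meshing produced inverted tets")
  attr(m, "quality") <- q
  m
}

## ---- element measures and quality ----------------------------------------

tri_areas <- function(nodes, tri) {
  a <- tri[, 1]; b <- tri[, 2]; cc <- tri[, 3]
  0.5 * ((nodes[b, 1] - nodes[a, 1]) * (nodes[cc, 2] - nodes[a, 2]) -
         (nodes[b, 2] - nodes[a, 2]) * (nodes[cc, 1] - nodes[a, 1]))
}

tet_volumes <- function(nodes, tet) {
  a <- nodes[tet[, 1], , drop = FALSE]
  u <- nodes[tet[, 2], , drop = FALSE] - a
  v <- nodes[tet[, 3], , drop = FALSE] - a
  w <- nodes[tet[, 4], , drop = FALSE] - a
  (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
   u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
   u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
}

## quad corner Jacobians (bilinear map), min over the 4 corners per element
quad_corner_jacobians <- function(nodes, quad) {
  out <- matrix(0, nrow(quad), 4)
  for (k in 1:4) {
    a <- quad[, k]; b <- quad[, (k %% 4) + 1]; d <- quad[, ((k + 2) %% 4) + 1]
    out[, k] <- (nodes[b, 1] - nodes[a, 1]) * (nodes[d, 2] - nodes[a, 2]) -
                (nodes[b, 2] - nodes[a, 2]) * (nodes[d, 1] - nodes[a, 1])
  }
  out
}

#' Minimal element quality of a mesh
#'
#' Reports the minimal (signed) element Jacobian measure: twice the triangle
#' area, the minimal corner Jacobian of each quadrilateral, and six times the
#' tetrahedron volume. Any non-positive value flags an inverted element.
#'
#' @param mesh an `lv_mesh`.
#' @return list with `min_jacobian`, `min_measure` (smallest element
#'   area/volume) and `n_elements`.
#' @export
mesh_quality <- function(mesh) {
  j <- numeric(0); meas <- numeric(0)
  if (nrow(mesh$tri)) { a <- tri_areas(mesh$nodes, mesh$tri); j <- c(j, 2 * a); meas <- c(meas, a) }
  if (nrow(mesh$quad)) {
    cj <- quad_corner_jacobians(mesh$nodes, mesh$quad)
    j <- c(j, apply(cj, 1, min)); meas <- c(meas, rowSums(cj) / 4)
  }
  if (nrow(mesh$tet)) { v <- tet_volumes(mesh$nodes, mesh$tet); j <- c(j, 6 * v); meas <- c(meas, v) }
  list(min_jacobian = min(j), min_measure = min(meas), n_elements = length(meas))
}

#' Area (2D) or volume (3D) enclosed by a mesh
#'
#' Sum of element measures: triangle/quadrilateral areas in 2D, tetrahedron
#' volumes in 3D.
#' @param mesh an `lv_mesh`.
#' @return scalar, in squared (2D) or cubed (3D) mesh units.
#' @export
mesh_measure <- function(mesh) {
  tot <- 0
  if (nrow(mesh$tri)) tot <- tot + sum(tri_areas(mesh$nodes, mesh$tri))
  if (nrow(mesh$quad)) {
    cj <- quad_corner_jacobians(mesh$nodes, mesh$quad)
    tot <- tot + sum(rowSums(cj) / 4)
  }
  if (nrow(mesh$tet)) tot <- tot + sum(tet_volumes(mesh$nodes, mesh$tet))
  tot
}
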