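## Moving lumen geometry: cardiac-cycle timing, 2D keyframe boundary motion,
## 3D ring reconstruction and ED/ES correspondence surfaces.
##
## Model frame convention (used by everything downstream): the open IO
## boundary lies in the plane {y = 0} (2D) or {z = 0} (3D); the apex points
## toward negative y/z; the "vertical" (base-to-apex) axis used for the
## hemodynamic force is +y (2D) or +z (3D), positive toward the base.

#' Cardiac-cycle timing
#'
#' Normalized cycle time T in [0, 1] with T = 0 (and 1) at end diastole and
#' T = `systole_fraction` at end systole. Physical time is
#' t = T * 60 / heart_rate seconds.
#'
#' @param systole_fraction fraction of the cycle in systole (default 0.4).
#' @param heart_rate beats per minute (default 60).
#' @return object of class `lv_cycle_phase`.
#' @export
cycle_phase <- function(systole_fraction = 0.4, heart_rate = 60) {
  if (systole_fraction <= 0 || systole_fraction >= 1)
    stopf("systole_fraction must be in (0,1)")
  if (heart_rate <= 0) stopf("heart_rate must be positive")
  structure(list(systole_fraction = systole_fraction, heart_rate = heart_rate),
            class = "lv_cycle_phase")
}

#' Contraction weight s(T) of the two-phase (ED/ES) motion law
#'
#' Piecewise linear: s(0) = 0, s(systole_fraction) = 1, s(1) = 0, so node
#' positions are x(T) = x_ED + s(T) (x_ES - x_ED).
#'
#' @param T normalized cycle time (vectorized); values outside [0,1] wrap.
#' @param cycle a [cycle_phase()].
#' @return numeric vector of weights in [0, 1].
#' @export
phase_weight <- function(T, cycle = cycle_phase()) {
  T <- T %% 1
  sf <- cycle$systole_fraction
  ifelse(T <= sf, T / sf, (1 - T) / (1 - sf))
}

## ---- 2D keyframe motion --------------------------------------------------

## Clip a closed trace (CCW, mm) against y <= 0 and return the open wall
## polyline from the left IO endpoint to the right one.
wall_from_trace <- function(pts, tol = 1e-9) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  y <- pts[, 2]
  if (all(y > -tol)) stopf("trace does not reach the IO line y = 0")
  nxt <- c(2:n, 1)
  cross_idx <- which((y > tol & y[nxt] < -tol) | (y < -tol & y[nxt] > tol))
  if (length(cross_idx) != 2)
    stopf("trace must cross y = 0 exactly twice, found %d crossings", length(cross_idx))
  cross_pt <- t(vapply(cross_idx, function(i) {
    j <- nxt[i]
    a <- y[i] / (y[i] - y[j])
    pts[i, ] + a * (pts[j, ] - pts[i, ])
  }, numeric(2)))
  ## walk the arc with negative y
  path_from <- function(ci) {
    j <- nxt[cross_idx[ci]]
    out <- cross_pt[ci, , drop = FALSE]
    while (TRUE) {
      if (y[j] < -tol) out <- rbind(out, pts[j, ])
      else break
      j <- nxt[j]
    }
    rbind(out, cross_pt[-ci, ][1:2])
  }
  w <- if (y[nxt[cross_idx[1]]] < -tol) path_from(1) else path_from(2)
  w[1, 2] <- 0; w[nrow(w), 2] <- 0
  if (w[1, 1] > w[nrow(w), 1]) w <- w[nrow(w):1, , drop = FALSE]
  w
}

#' Build a 2D moving-boundary geometry from keyframe traces
#'
#' Takes the (typically 8) traced lumen outlines of one long-axis plane at
#' known cycle phases, clips each to the half-plane below the IO line y = 0,
#' resamples all wall polylines to a common point count by arclength from the
#' left IO endpoint, and returns a piecewise-linear-in-time nodal motion law.
#'
#' @param traces list of closed polylines (mm, model frame, counter-clockwise)
#'   each crossing y = 0 exactly twice.
#' @param times normalized cycle times of the keyframes; must include 0 (end
#'   diastole); the keyframe at end systole marks peak contraction.
#' @param n_points common wall point count after resampling (default 96).
#' @param cycle a [cycle_phase()].
#' @param check_simple number of sampled T values at which interpolated
#'   polygons are checked for self-intersection (0 to skip).
#' @return object of class `lv_motion2d` with `$wall_at(T)` (open wall
#'   polyline, mm), `$area_at(T)` (mm^2) and keyframe data.
#' @export
build_motion_2d <- function(traces, times, n_points = 96, cycle = cycle_phase(),
                            check_simple = 50) {
  if (length(traces) != length(times)) stopf("traces and times lengths differ")
  if (length(traces) < 2) stopf("need at least 2 keyframes")
  if (!any(abs(times) < 1e-12)) stopf("keyframes must include T = 0 (end diastole)")
  ord <- order(times)
  times <- times[ord]; traces <- traces[ord]
  walls <- lapply(traces, function(tr) {
    w <- wall_from_trace(as.matrix(tr))
    w <- resample_polyline(w, n_points, closed = FALSE)
    w[c(1, n_points), 2] <- 0
    w
  })
  karr <- array(unlist(walls), dim = c(n_points, 2, length(walls)))
  ## periodic closure at T = 1
  ktimes <- c(times, 1)
  karr <- array(c(karr, walls[[1]]), dim = c(n_points, 2, length(walls) + 1))
  wall_at <- function(T) {
    T <- T %% 1
    k <- findInterval(T, ktimes, rightmost.closed = TRUE)
    t0 <- ktimes[k]; t1 <- ktimes[k + 1]
    a <- if (t1 > t0) (T - t0) / (t1 - t0) else 0
    (1 - a) * karr[, , k] + a * karr[, , k + 1]
  }
  area_at <- function(T) abs(polygon_area(wall_at(T)))
  if (check_simple > 0) {
    for (T in seq(0, 1, length.out = check_simple)) {
      if (!polygon_is_simple(wall_at(T)))
        stopf("interpolated boundary self-intersects at T = %.3f", T)
    }
  }
  structure(list(keyframes = karr, times = ktimes, n_points = n_points,
                 cycle = cycle, wall_at = wall_at, area_at = area_at),
            class = "lv_motion2d")
}

#' @export
print.lv_motion2d <- function(x, ...) {
  cat(sprintf("<lv_motion2d> %d keyframes, %d wall points; area ED %.1f mm^2, min %.1f mm^2\n",
              length(x$times) - 1, x$n_points, x$area_at(0),
              min(vapply(seq(0, 1, 0.02), x$area_at, 1))))
  invisible(x)
}

## ---- 3D reconstruction ---------------------------------------------------

#' Stack traced short-axis contours into 3D rings
#'
#' Maps per-slice lumen traces (pixel coordinates) into patient space using
#' the DICOM geometry, rotates them into the model frame (IO plane z = 0,
#' apex toward negative z), orders the rings base to apex, and resamples each
#' ring to a common point count with a consistent angular datum: index 0 sits
#' where the ring crosses the ray from its centroid along the model +x axis,
#' proceeding counter-clockwise (viewed from the base).
#'
#' @param traces list of traces (objects with `$points` pixel polylines, or
#'   plain matrices), one per slice, all at the same cardiac phase.
#' @param stack the [load_cine_stack()] `lv_image_stack` the traces came from.
#' @param slices slice indices corresponding to `traces`.
#' @param n_theta common ring point count (default 24).
#' @param frame optional patient-to-model frame (`$origin`, `$rotation`,
#'   `$apexward`) from a previous reconstruction; rings at different phases
#'   must share one frame so their nodes correspond (pass the end-diastolic
#'   result's frame when reconstructing end systole).
#' @param smooth_theta,smooth_levels odd moving-average windows applied to
#'   the resampled rings along the contour and across slices (the
#'   spatial trace smoothing pass; 1 = off).
#' @return object of class `lv_rings3d`: `rings` array L x n_theta x 3 (mm,
#'   model frame, level 1 = base), `spacing` (mean inter-ring distance, mm),
#'   and the patient-to-model `frame`.
#' @export
reconstruct_3d_contours <- function(traces, stack, slices = seq_along(traces),
                                    n_theta = 24, frame = NULL,
                                    smooth_theta = 5, smooth_levels = 3) {
  if (length(traces) < 3) stopf("need at least 3 slices with accepted traces")
  pts3 <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    pp <- if (is.list(tr) && !is.null(tr$points)) tr$points else as.matrix(tr)
    pixel_to_patient(stack, slices[i], pp)
  })
  ## stack normal: row x col direction cosines of the first slice
  o <- stack$slice_orientations[[slices[1]]]
  nrm <- c(o$row[2] * o$col[3] - o$row[3] * o$col[2],
           o$row[3] * o$col[1] - o$row[1] * o$col[3],
           o$row[1] * o$col[2] - o$row[2] * o$col[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  cents <- t(vapply(pts3, colMeans, numeric(3)))
  if (is.null(frame)) {
    z <- cents %*% nrm
    ## base = the end with the larger ring (LV tapers toward the apex)
    areas <- vapply(pts3, function(p) {
      abs(polygon_area(cbind((p - rep(colMeans(p), each = nrow(p))) %*% pick_plane_basis(nrm))))
    }, 1)
    corv <- suppressWarnings(stats::cor(as.numeric(z), areas))
    ## untapered stacks (e.g. cylinders) have no preferred end: pick one
    apexward <- if (is.na(corv) || corv < 0) 1 else -1
    nrm_apex <- apexward * nrm                    # points base -> apex
    ## model frame: ez = -apexward normal (so apex at negative z)
    ez <- -nrm_apex
    B <- pick_plane_basis(ez)                     # 3 x 2: ex, ey in IO plane
    ex <- B[, 1]; ey <- ez_cross(ez, ex)
    ordz <- order(as.numeric(cents %*% nrm_apex)) # base first ... apex last
    origin <- cents[ordz[1], ]
    frame <- list(origin = origin, rotation = cbind(ex, ey, ez),
                  apexward = nrm_apex)
  } else {
    ordz <- order(as.numeric(cents %*% frame$apexward))
  }
  if (!identical(ordz, seq_along(pts3)))
    warnf("slices were out of order along the stack normal; re-sorted")
  pts3 <- pts3[ordz]
  R <- frame$rotation
  rings <- array(0, c(length(pts3), n_theta, 3))
  for (l in seq_along(pts3)) {
    q <- (pts3[[l]] - rep(frame$origin, each = nrow(pts3[[l]]))) %*% R
    ## smooth along the contour at native trace resolution, then resample
    if (smooth_theta > 1 && nrow(q) > 2 * smooth_theta) {
      for (d in 1:3) q[, d] <- circular_moving_average(q[, d], smooth_theta)
    }
    rings[l, , ] <- resample_ring(q, n_theta)
  }
  L <- dim(rings)[1]
  if (smooth_levels > 1 && L >= 3) {
    ## smooth in-plane coordinates only: slice z positions are metadata
    h <- (smooth_levels - 1) / 2
    sm <- rings
    for (l in seq_len(L)) {
      lo <- max(1, l - h); hi <- min(L, l + h)
      sm[l, , 1:2] <- apply(rings[lo:hi, , 1:2, drop = FALSE], c(2, 3), mean)
    }
    rings <- sm
  }
  zs <- vapply(seq_len(L), function(l) mean(rings[l, , 3]), 1)
  structure(list(rings = rings, spacing = mean(abs(diff(zs))),
                 frame = frame, n_theta = n_theta),
            class = "lv_rings3d")
}

ez_cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])

## orthonormal in-plane basis for a unit normal; first vector is the
## projection of patient +x (falls back to +y near degeneracy)
pick_plane_basis <- function(nrm) {
  ex <- c(1, 0, 0) - sum(c(1, 0, 0) * nrm) * nrm
  if (sqrt(sum(ex^2)) < 1e-6) ex <- c(0, 1, 0) - sum(c(0, 1, 0) * nrm) * nrm
  ex <- ex / sqrt(sum(ex^2))
  cbind(ex, ez_cross(nrm, ex))
}

## Resample a 3D ring (points roughly in a z = const plane, model frame) to
## n_theta points, CCW in (x, y), arclength-uniform, index 1 on the +x ray.
resample_ring <- function(q, n_theta) {
  cen <- colMeans(q)
  xy <- sweep(q[, 1:2, drop = FALSE], 2, cen[1:2])
  if (polygon_area(xy) < 0) { q <- q[nrow(q):1, , drop = FALSE]; xy <- xy[nrow(xy):1, , drop = FALSE] }
  ## find crossing of the +x ray (y changes sign with x > 0)
  n <- nrow(xy)
  nxt <- c(2:n, 1)
  cand <- which(xy[, 2] <= 0 & xy[nxt, 2] > 0 & (xy[, 1] > 0 | xy[nxt, 1] > 0))
  if (!length(cand)) cand <- which.max(xy[, 1])
  i0 <- cand[1]
  j <- nxt[i0]
  a <- if (abs(xy[j, 2] - xy[i0, 2]) > 1e-12) -xy[i0, 2] / (xy[j, 2] - xy[i0, 2]) else 0
  start <- q[i0, ] + a * (q[j, ] - q[i0, ])
  ord <- ((seq_len(n) + i0 - 1L) %% n) + 1L       # j, j+1, ..., wrap ..., i0
  ring <- rbind(start, q[ord, , drop = FALSE])
  resample_polyline(ring, n_theta, closed = TRUE)
}

#' Corresponding ED/ES shell surfaces of the LV lumen
#'
#' Builds the moving lumen surface from ring stacks at end diastole and end
#' systole. The body is a structured quadrilateral (ring x angle) grid split
#' into triangles; the apex is closed by a fan of curved triangular patches
#' (grouped in four quadrants) converging to the apex point. The identical
#' construction order at both phases makes the meshes index-correspondent:
#' same node and element counts, node i at ED maps to node i at ES.
#'
#' @param rings_ed,rings_es `lv_rings3d` objects (or plain L x n_theta x 3
#'   arrays) with identical dimensions.
#' @param spacing inter-slice spacing (mm), used to place the apex half a
#'   spacing below the apical ring centroid when no apex is given.
#' @param apex_ed,apex_es optional explicit apex points (mm, model frame).
#' @param cycle a [cycle_phase()].
#' @param weight,dweight optional custom contraction weight s(T) and its
#'   derivative ds/dT, replacing the piecewise-linear [phase_weight()] law.
#' @return object of class `lv_motion3d`: node arrays `nodes_ed`/`nodes_es`,
#'   shared triangles `tris`, `io_ring` node ids, ring bookkeeping, and
#'   `$volume_at(T)` (mm^3).
#' @export
build_corresponding_surfaces <- function(rings_ed, rings_es, spacing = NULL,
                                         apex_ed = NULL, apex_es = NULL,
                                         cycle = cycle_phase(),
                                         weight = NULL, dweight = NULL) {
  gr <- function(x) if (inherits(x, "lv_rings3d")) x$rings else x
  sp <- spacing %||% (if (inherits(rings_ed, "lv_rings3d")) rings_ed$spacing else
    stopf("spacing required when rings are plain arrays"))
  red <- gr(rings_ed); res <- gr(rings_es)
  if (!identical(dim(red), dim(res)))
    stopf("ED and ES ring stacks differ in shape (%s vs %s)",
          paste(dim(red), collapse = "x"), paste(dim(res), collapse = "x"))
  L <- dim(red)[1]; nt <- dim(red)[2]
  apex_of <- function(r, ap) {
    if (!is.null(ap)) return(ap)
    cen <- colMeans(r[L, , ])
    cen + c(0, 0, -sp / 2)
  }
  aed <- apex_of(red, apex_ed); aes <- apex_of(res, apex_es)
  nodes_of <- function(r, ap) rbind(matrix(aperm(r, c(2, 1, 3)), ncol = 3), ap)
  nodes_ed <- nodes_of(red, aed); nodes_es <- nodes_of(res, aes)
  nid <- function(l, j) (l - 1L) * nt + ((j - 1L) %% nt) + 1L
  apex_id <- L * nt + 1L
  tris <- vector("list", L)
  for (l in seq_len(L - 1L)) {
    j <- seq_len(nt)
    a <- nid(l, j); b <- nid(l, j + 1); A <- nid(l + 1, j); B <- nid(l + 1, j + 1)
    tris[[l]] <- rbind(cbind(a, b, B), cbind(a, B, A))
  }
  tris[[L]] <- cbind(nid(L, seq_len(nt)), nid(L, seq_len(nt) + 1), apex_id)
  tris <- do.call(rbind, tris)
  apex_patch <- ((seq_len(nt) - 1L) %/% (nt / 4)) + 1L     # 4 quadrant patches
  wfun <- weight %||% function(T) phase_weight(T, cycle)
  volume_at <- function(T) {
    s <- wfun(T)
    surface_enclosed_volume(nodes_ed + s * (nodes_es - nodes_ed), tris)
  }
  structure(list(nodes_ed = nodes_ed, nodes_es = nodes_es, tris = tris,
                 io_ring = nid(1, seq_len(nt)), apex_id = apex_id,
                 rings_ed = red, rings_es = res, apex_ed = aed, apex_es = aes,
                 spacing = sp, n_levels = L, n_theta = nt, cycle = cycle,
                 weight = weight, dweight = dweight,
                 apex_patch = apex_patch, volume_at = volume_at),
            class = "lv_motion3d")
}

#' @export
print.lv_motion3d <- function(x, ...) {
  cat(sprintf("<lv_motion3d> %d rings x %d points + apex; V_ED = %.1f mL, V_ES = %.1f mL\n",
              x$n_levels, x$n_theta, x$volume_at(0) / 1000,
              x$volume_at(x$cycle$systole_fraction) / 1000))
  invisible(x)
}

## Signed volume enclosed by a triangulated surface with the IO opening
## capped by a fan to the opening centroid (divergence theorem).
surface_enclosed_volume <- function(nodes, tris, io_ring = NULL) {
  vol_tris <- function(nd, tr) {
    a <- nd[tr[, 1], , drop = FALSE]; b <- nd[tr[, 2], , drop = FALSE]
    cc <- nd[tr[, 3], , drop = FALSE]
    sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
        a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
        a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
  }
  v <- vol_tris(nodes, tris)
  if (!is.null(io_ring)) {
    cen <- colMeans(nodes[io_ring, , drop = FALSE])
    nt <- length(io_ring)
    cap <- cbind(io_ring, io_ring[c(2:nt, 1)], nrow(nodes) + 1L)
    v <- v + vol_tris(rbind(nodes, cen), cap)
  }
  abs(v)
}

#' Displaced LV surface and wall velocity at cycle time T
#'
#' Linear ED/ES interpolation: x(T) = x_ED + s(T) (x_ES - x_ED) with the
#' piecewise-linear [phase_weight()] law (contraction over systole, recovery
#' over diastole). The nodal velocity is the exact derivative of this law.
#'
#' @param geom an `lv_motion3d`.
#' @param T normalized cycle time in [0, 1].
#' @return list with `nodes` (mm), `velocity` (mm/s) and `tris`.
#' @export
interpolate_motion_3d <- function(geom, T) {
  d <- geom$nodes_es - geom$nodes_ed
  cyc_s <- 60 / geom$cycle$heart_rate
  sf <- geom$cycle$systole_fraction
  Tw <- T %% 1
  if (!is.null(geom$weight)) {
    s <- geom$weight(T)
    dsdT <- if (!is.null(geom$dweight)) geom$dweight(T) else NA_real_
  } else {
    s <- phase_weight(T, geom$cycle)
    dsdT <- if (Tw < sf) 1 / sf else -1 / (1 - sf)
  }
  list(nodes = geom$nodes_ed + s * d, velocity = d * (dsdT / cyc_s),
       tris = geom$tris)
}

## ---- lumen measure & motion objects for the solver -----------------------

#' Lumen area (2D) or volume (3D)
#'
#' Area of the interpolated boundary polygon by the shoelace formula (2D
#' motion), enclosed volume by the divergence theorem over the triangulated
#' surface with the IO capped (3D motion), or summed element measures for a
#' mesh / flow state.
#'
#' @param x an `lv_motion2d`, `lv_motion3d`, `lv_mesh` or `lv_flow_state`.
#' @param T normalized cycle time (motion objects only).
#' @return mm^2 or mm^3 (meshes in their own units).
#' @export
lumen_measure <- function(x, T = 0) UseMethod("lumen_measure")

#' @export
lumen_measure.lv_motion2d <- function(x, T = 0) x$area_at(T)

#' @export
lumen_measure.lv_motion3d <- function(x, T = 0) x$volume_at(T)

#' @export
lumen_measure.lv_mesh <- function(x, T = 0) abs(mesh_measure(x))

#' @export
lumen_measure.lv_flow_state <- function(x, T = 0) abs(mesh_measure(x$mesh))

#' Volume mesh of the lumen at end diastole
#'
#' 2D: quadrilateral-dominant transfinite mesh of the region between the IO
#' chord and the wall trace. 3D: structured tetrahedral mesh built from the
#' ring stack. The minimal element quality is attached as attribute
#' `quality`.
#'
#' @param geom `lv_motion2d` or `lv_motion3d`.
#' @param n_layers 2D: element layers between IO and wall.
#' @param n_radial 3D: radial node layers.
#' @param subsample_theta 3D: keep every k-th angular point of the surface
#'   rings for the volume mesh (the surface itself stays at full resolution;
#'   `n_theta` must be divisible by k).
#' @return an `lv_mesh` (mm).
#' @export
mesh_lumen <- function(geom, n_layers = 10, n_radial = 4, subsample_theta = 2) {
  if (inherits(geom, "lv_motion2d")) {
    mesh_lumen2d(geom$wall_at(0), n_layers = n_layers)
  } else if (inherits(geom, "lv_motion3d")) {
    ts <- theta_subset(geom$n_theta, subsample_theta)
    mesh_lumen3d(geom$rings_ed[, ts, , drop = FALSE], geom$apex_ed,
                 n_radial = n_radial)
  } else stopf("unsupported geometry of class %s", paste(class(geom), collapse = "/"))
}

theta_subset <- function(nt, k) {
  if (k < 1 || nt %% k != 0) stopf("n_theta (%d) must be divisible by subsample_theta (%d)", nt, k)
  seq(1, nt, by = k)
}

#' Couple a moving geometry to a solver-ready motion object
#'
#' Builds the end-diastolic lumen mesh and a wall-position law aligned with
#' the mesh's wall boundary nodes, the form consumed by [solve_cycle()].
#'
#' @param geom `lv_motion2d` or `lv_motion3d`.
#' @param n_layers,n_radial,subsample_theta mesh resolution, see
#'   [mesh_lumen()].
#' @return object of class `lv_lumen_motion`: `mesh` (mm), `wall_nodes`,
#'   `wall_pos(T)` (mm), `cycle`, `geom`.
#' @export
lumen_motion <- function(geom, n_layers = 10, n_radial = 4, subsample_theta = 2) {
  mesh <- mesh_lumen(geom, n_layers = n_layers, n_radial = n_radial,
                     subsample_theta = subsample_theta)
  wn <- boundary_nodes(mesh, "wall")
  if (inherits(geom, "lv_motion2d")) {
    wi <- attr(mesh, "wall_index")
    perm <- match(wn, wi)
    if (anyNA(perm)) stopf("internal: wall nodes not aligned with trace points")
    wall_pos <- function(T) geom$wall_at(T)[perm, , drop = FALSE]
  } else {
    ri <- attr(mesh, "ring_index")            # L x nt_sub node ids
    ai <- attr(mesh, "apex_index")
    ts <- theta_subset(geom$n_theta, subsample_theta)
    ## surface node index of ring point (l, ts[j]) in the full node arrays
    surf_idx <- as.integer(t(outer((seq_len(geom$n_levels) - 1L) * geom$n_theta,
                                   ts, "+")))
    ids <- c(as.integer(t(ri)), ai)           # mesh node id per selected node
    srcs <- c(surf_idx, nrow(geom$nodes_ed))  # apex is the last surface node
    keep <- !is.na(ids)
    perm0 <- match(wn, ids[keep])
    if (anyNA(perm0)) stopf("internal: wall nodes not covered by ring/apex nodes")
    src_of_wn <- srcs[keep][perm0]
    wall_pos <- function(T) {
      mv <- interpolate_motion_3d(geom, T)
      mv$nodes[src_of_wn, , drop = FALSE]
    }
  }
  structure(list(mesh = mesh, wall_nodes = wn, wall_pos = wall_pos,
                 cycle = geom$cycle, geom = geom),
            class = "lv_lumen_motion")
}
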