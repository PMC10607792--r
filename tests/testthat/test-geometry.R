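circle_trace <- function(r, n = 96) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)] + pi / n
  cbind(r * cos(th), -r * sin(th))
}

test_that("cycle timing maps normalized time to the systole/diastole split", {
  cyc <- cycle_phase(0.4, 60)
  expect_equal(phase_weight(c(0, 0.4, 1), cyc), c(0, 1, 0))
  expect_equal(phase_weight(0.2, cyc), 0.5)
  expect_equal(phase_weight(0.7, cyc), 0.5)
  expect_error(cycle_phase(1.2), "systole_fraction")
  expect_error(cycle_phase(0.4, -10), "heart_rate")
})

test_that("2D keyframe motion interpolates node positions linearly", {
  g <- build_motion_2d(list(circle_trace(20), circle_trace(15)),
                       times = c(0, 0.4))
  w <- g$wall_at(0.2)
  r <- sqrt(rowSums(w^2))
  expect_equal(r, rep(17.5, nrow(w)), tolerance = 1e-3)
  ## identical keyframes: motion is identically zero
  g0 <- build_motion_2d(list(circle_trace(20), circle_trace(20)),
                        times = c(0, 0.4))
  expect_equal(g0$wall_at(0.63), g0$wall_at(0), tolerance = 1e-12)
  ## area(T) equals the shoelace area of the interpolated polygon and is
  ## continuous in T
  Ts <- seq(0, 1, length.out = 501)
  areas <- vapply(Ts, g$area_at, 1)
  expect_equal(areas[1], abs(polygon_area(g$wall_at(0))))
  expect_lt(max(abs(diff(areas))), 0.01 * diff(range(areas)))
})

test_that("traces that do not reach the IO line are rejected", {
  low <- cbind(circle_trace(10)[, 1], circle_trace(10)[, 2] - 30)
  expect_error(build_motion_2d(list(low, low), times = c(0, 0.4)), "cross|reach")
  expect_error(build_motion_2d(list(circle_trace(20)), times = 0), "at least 2")
})

test_that("short-axis rings reconstruct a cylinder in patient space", {
  ## synthetic stack: 4 slices, disk of radius 15 mm; traces from the masks
  spec <- phantom_spec("image_stack", seed = 9, n_slices = 4, n_phases = 2,
                       rows = 96, cols = 96, r_base = 15, taper = 1,
                       contraction = 0, wall_thickness = 6)
  dir <- tempfile("cyl")
  ph <- make_image_stack(spec, dir = dir)
  st <- load_cine_stack(ph$files)[[1]]
  traces <- lapply(1:4, function(s) extract_and_filter_traces(ph$masks[[s]][[1]]))
  rings <- reconstruct_3d_contours(traces, st, n_theta = 32)
  expect_equal(dim(rings$rings), c(4, 32, 3))
  expect_equal(rings$spacing, 8, tolerance = 1e-9)
  for (l in 1:4) {
    ring <- rings$rings[l, , ]
    cen <- colMeans(ring)
    rad <- sqrt(rowSums(sweep(ring[, 1:2], 2, cen[1:2])^2))
    expect_lt(abs(mean(rad) - 15), 0.5)           # fitted-circle radius
    expect_lt(max(abs(rad - 15)), 1)              # pointwise rasterization wobble
    expect_equal(mean(ring[, 3]), -8 * (l - 1), tolerance = 1e-6)
  }
  expect_error(reconstruct_3d_contours(traces[1], st), "at least 3")
})

test_that("tilted stacks reconstruct with the same inter-ring spacing", {
  ## rotate the acquisition 30 degrees about x: normal tilts identically
  ang <- 30 * pi / 180
  rowd <- c(1, 0, 0)
  cold <- c(0, cos(ang), sin(ang))
  nrm <- c(0, -sin(ang), cos(ang))
  dir <- tempfile("tilt"); dir.create(dir)
  img <- matrix(20, 64, 64)
  rr <- matrix(rep(0:63, 64), 64, 64); cc <- matrix(rep(0:63, each = 64), 64, 64)
  mask <- sqrt((rr - 31.5)^2 + (cc - 31.5)^2) <= 12 / 0.7
  img[mask] <- 200
  fs <- character(0)
  for (s in 1:3) for (p in 1:2) {
    f <- file.path(dir, sprintf("t%d_%d.dcm", s, p))
    write_dicom_frame(f, img, pixel_spacing = c(0.7, 0.7),
                      image_position = -8 * (s - 1) * nrm,
                      image_orientation = c(rowd, cold),
                      instance_number = (s - 1) * 2 + p,
                      trigger_time = 100 * (p - 1),
                      sop_uid = sprintf("2.25.88.%d.%d", s, p))
    fs <- c(fs, f)
  }
  st <- load_cine_stack(fs)[[1]]
  tr <- extract_and_filter_traces(mask)
  rings <- suppressWarnings(                      # slice order warning is fine
    reconstruct_3d_contours(list(tr, tr, tr), st, n_theta = 24,
                            smooth_levels = 1))
  zs <- vapply(1:3, function(l) mean(rings$rings[l, , 3]), 1)
  expect_equal(abs(diff(zs)), c(8, 8), tolerance = 1e-6)
  ## rings are planar and parallel to the (tilted) acquisition plane
  expect_lt(max(abs(rings$rings[2, , 3] - zs[2])), 1e-6)
})

test_that("ED/ES correspondence surfaces share connectivity and differ radially", {
  bc <- make_benchmark_case(phantom_spec("contracting_cylinder",
                                         n_levels = 6, n_theta = 24))
  g <- bc$motion$geom
  expect_identical(dim(g$nodes_ed), dim(g$nodes_es))
  expect_identical(nrow(g$tris), nrow(g$tris))    # shared element table
  d <- g$nodes_es - g$nodes_ed
  ## every node moves only radially, by R_ED - R_ES = 3 mm (apex fixed)
  body <- seq_len(nrow(d) - 1)
  radial <- sqrt(rowSums(d[body, 1:2, drop = FALSE]^2))
  moving <- radial > 1e-9
  expect_equal(unname(radial[moving]), rep(3, sum(moving)), tolerance = 0.1)
  expect_lt(max(abs(d[, 3])), 1e-9)
  ## mismatched ring stacks are refused
  expect_error(build_corresponding_surfaces(g$rings_ed[1:4, , ], g$rings_es,
                                            spacing = 10),
               "differ in shape")
})

test_that("surface-enclosed volume matches a brute-force signed-tetra oracle", {
  bc <- make_benchmark_case(phantom_spec("half_ellipsoid_lv",
                                         n_levels = 10, n_theta = 24))
  g <- bc$motion$geom
  nodes <- g$nodes_ed; tris <- g$tris
  ## oracle: sum of signed tetrahedra against the origin, io capped by fan
  cen <- colMeans(nodes[g$io_ring, ])
  nd2 <- rbind(nodes, cen)
  nt <- length(g$io_ring)
  cap <- cbind(g$io_ring, g$io_ring[c(2:nt, 1)], nrow(nd2))
  allt <- rbind(tris, cap)
  vol <- 0
  for (i in seq_len(nrow(allt))) {
    a <- nd2[allt[i, 1], ]; b <- nd2[allt[i, 2], ]; cc <- nd2[allt[i, 3], ]
    vol <- vol + sum(a * c(b[2] * cc[3] - b[3] * cc[2],
                           b[3] * cc[1] - b[1] * cc[3],
                           b[1] * cc[2] - b[2] * cc[1])) / 6
  }
  expect_equal(g$volume_at(0), abs(vol), tolerance = 0.02)
})

test_that("ED/ES interpolation hits the endpoints and the exact velocity", {
  bc <- make_benchmark_case(phantom_spec("half_ellipsoid_lv",
                                         n_levels = 8, n_theta = 16))
  g <- bc$motion$geom
  expect_equal(interpolate_motion_3d(g, 0)$nodes, g$nodes_ed)
  expect_equal(interpolate_motion_3d(g, 0.4)$nodes, g$nodes_es)
  expect_equal(interpolate_motion_3d(g, 0.2)$nodes,
               (g$nodes_ed + g$nodes_es) / 2)
  ## systolic nodal speed = |x_ES - x_ED| / (0.4 * cycle duration)
  mv <- interpolate_motion_3d(g, 0.1)
  expect_equal(sqrt(rowSums(mv$velocity^2)),
               sqrt(rowSums((g$nodes_es - g$nodes_ed)^2)) / 0.4,
               tolerance = 1e-12)
})

test_that("lumen meshes partition their boundary and refine as expected", {
  m <- mesh_rect2d(0, 1, 0, 1, 8, 8, io = "top")
  expect_identical(sort(unique(m$btag)), c("io", "wall"))
  expect_identical(length(m$btag), 32L)           # all edges tagged
  ## 2D refinement: halving h quadruples the cell count (~)
  g <- phantom_motion_2d(n_pts = 256)
  m1 <- lvflow:::mesh_lumen2d(resample_polyline(g$wall_at(0), 49), n_layers = 6)
  m2 <- lvflow:::mesh_lumen2d(resample_polyline(g$wall_at(0), 97), n_layers = 12)
  r2 <- lvflow:::n_elements(m2) / lvflow:::n_elements(m1)
  expect_gt(r2, 4 * 0.7); expect_lt(r2, 4 * 1.3)
  ## 3D refinement: halving h gives ~8x more tets
  s1 <- phantom_spec("half_ellipsoid_lv", n_levels = 8, n_theta = 16)
  s2 <- phantom_spec("half_ellipsoid_lv", n_levels = 16, n_theta = 32)
  m3a <- mesh_lumen3d(lvflow:::.ellipsoid_rings(80, 25, 8, 16),
                      c(0, 0, -80), n_radial = 2)
  m3b <- mesh_lumen3d(lvflow:::.ellipsoid_rings(80, 25, 16, 32),
                      c(0, 0, -80), n_radial = 4)
  r3 <- nrow(m3b$tet) / nrow(m3a$tet)
  expect_gt(r3, 8 * 0.7); expect_lt(r3, 8 * 1.3)
})

test_that("the structured tet mesh is conforming and uninverted", {
  bc <- make_benchmark_case(phantom_spec("contracting_cylinder",
                                         n_levels = 6, n_theta = 24))
  m <- bc$motion$mesh
  faces <- do.call(rbind, lapply(list(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(3, 1, 4)),
                                 function(p) m$tet[, p]))
  key <- apply(t(apply(faces, 1, sort)), 1, paste, collapse = "_")
  mult <- table(table(key))
  expect_identical(sort(names(mult)), c("1", "2"))   # boundary + interior only
  expect_identical(sum(key %in% names(which(table(key) == 1))),
                   nrow(m$bfaces))
  expect_gt(mesh_quality(m)$min_jacobian, 0)
})

test_that("lumen measures match closed forms", {
  ## half-disk of radius 20 mm: area pi r^2 / 2
  g <- phantom_motion_2d(r_ed = 20, r_es = 20, n_pts = 256)
  expect_equal(g$area_at(0), pi * 20^2 / 2, tolerance = 0.005)
  ## capped cylinder r = 15, L = 60: volume pi r^2 L
  bc <- make_benchmark_case(phantom_spec("contracting_cylinder"))
  expect_equal(lumen_measure(bc$motion$geom, 0), pi * 15^2 * 60,
               tolerance = 0.01)
  ## volume mesh agrees with the surface-enclosed measure
  mesh_v <- mesh_measure(bc$motion$mesh)
  surf_v <- lumen_measure(bc$motion$geom, 0)
  expect_equal(mesh_v / surf_v, 1, tolerance = 0.015)
})

test_that("interpolated geometry stays valid over 50 sampled phases", {
  for (kind in c("contracting_cylinder", "half_ellipsoid_lv")) {
    bc <- make_benchmark_case(phantom_spec(kind, n_levels = 8, n_theta = 16))
    mot <- bc$motion
    mesh0 <- lvflow:::mesh_in_meters(mot$mesh)
    ext <- lvflow:::make_extender(mesh0)
    wn <- mot$wall_nodes
    meas <- vapply(seq(0, 1, length.out = 50), function(T) {
      wp <- mot$wall_pos(T) * 1e-3
      m2 <- mesh0
      m2$nodes <- mesh0$nodes + ext(wp - mesh0$nodes[wn, , drop = FALSE])
      q <- mesh_quality(m2)
      expect_gt(q$min_jacobian, 0)
      lvflow:::mesh_measure(m2)
    }, 1)
    ## lumen measure continuous in T
    expect_lt(max(abs(diff(meas))), 0.12 * diff(range(meas)))
  }
})

test_that("2D harmonic-extended motion keeps the lumen mesh valid", {
  g <- phantom_motion_2d()
  mot <- lumen_motion(g, n_layers = 6)
  mesh0 <- lvflow:::mesh_in_meters(mot$mesh)
  ext <- lvflow:::make_extender(mesh0)
  wn <- mot$wall_nodes
  for (T in seq(0, 1, length.out = 21)) {
    wp <- mot$wall_pos(T) * 1e-3
    m2 <- mesh0
    m2$nodes <- mesh0$nodes + ext(wp - mesh0$nodes[wn, , drop = FALSE])
    expect_gt(mesh_quality(m2)$min_jacobian, 0)
  }
})
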