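test_that("kinetic-energy density follows its definition pointwise", {
  st <- rect_state(4, 4, function(p) c(0, 0))
  expect_equal(ke_density(st), rep(0, nrow(st$mesh$nodes)))
  st1 <- rect_state(4, 4, function(p) c(1, 0))
  expect_equal(ke_density(st1, fluid_props()),
               rep(530, nrow(st1$mesh$nodes)))   # 0.5 * 1060 * 1^2
  st2 <- rect_state(4, 4, function(p) c(2, 0))
  expect_equal(ke_density(st2), 4 * ke_density(st1))
})

test_that("the spatial KE average is exact for uniform and split fields", {
  ## uniform speed: mean KE independent of domain shape
  g <- phantom_motion_2d(r_ed = 20, r_es = 20)
  mot <- lumen_motion(g, n_layers = 6)
  m <- mesh_in_meters(mot$mesh)
  v0 <- 0.37
  st <- flow_state(m, matrix(c(v0, 0), nrow(m$nodes), 2, byrow = TRUE),
                   rep(0, nrow(m$nodes)))
  expect_equal(ke_average(st, fluid_props()), 0.5 * 1060 * v0^2,
               tolerance = 1e-12)
  ## half zero / half 530 J/m^3 with equal measure -> 265, up to the
  ## interface ramp of the nodal interpolation
  sth <- rect_state(100, 4, function(p) c(as.numeric(p[1] >= 0.5), 0))
  expect_equal(ke_average(sth, fluid_props()), 265, tolerance = 0.01)
  ## element quadrature against a dense midpoint oracle on an affine field
  sta <- rect_state(40, 40, function(p) c(0.2 + 0.5 * p[1] - 0.1 * p[2],
                                          0.3 * p[2]))
  ng <- 1000
  xs <- (seq_len(ng) - 0.5) / ng
  ke_or <- 0
  for (xi in xs) {
    vx <- 0.2 + 0.5 * xi - 0.1 * xs
    vy <- 0.3 * xs
    ke_or <- ke_or + sum(0.5 * 1060 * (vx^2 + vy^2))
  }
  ke_or <- ke_or / ng^2
  expect_equal(ke_average(sta, fluid_props()), ke_or, tolerance = 1e-3)
})

test_that("vorticity is exact for affine velocity fields", {
  ## rigid rotation omega = 1 rad/s about the origin: Omega_z = 2
  str <- rect_state(10, 10, function(p) c(-p[2], p[1]))
  vo <- vorticity(str)
  expect_equal(vo$elem, rep(2, length(vo$elem)), tolerance = 1e-12)
  av <- vorticity_averages(str)
  expect_equal(unname(av), c(2, 2), tolerance = 1e-12)
  ## uniform flow: zero vorticity
  stu <- rect_state(6, 6, function(p) c(0.4, 0.1))
  expect_lt(max(abs(vorticity(stu)$elem)), 1e-13)
  ## simple shear v_x = y: Omega_z = -1
  sts <- rect_state(6, 6, function(p) c(p[2], 0))
  expect_equal(vorticity(sts)$elem, rep(-1, length(vorticity(sts)$elem)),
               tolerance = 1e-12)
})

test_that("mirror-image vortex pairs balance to zero signed vorticity", {
  ## stream function sin(2 pi x) sin(pi y): two counter-rotating cells,
  ## mirror-symmetric about x = 1/2
  st <- rect_state(40, 20, function(p) {
    c(sin(2 * pi * p[1]) * pi * cos(pi * p[2]),
      -2 * pi * cos(2 * pi * p[1]) * sin(pi * p[2]))
  })
  av <- vorticity_averages(st)
  expect_lt(abs(av[["vort_avg"]]), 1e-10 * av[["vort_mag_avg"]])
  expect_gt(av[["vort_mag_avg"]], 1)
})

test_that("|signed average| never exceeds the magnitude average", {
  set.seed(7)
  for (k in 1:5) {
    st <- rect_state(8, 8, function(p) rnorm(2))
    av <- vorticity_averages(st)
    expect_lte(abs(av[["vort_avg"]]), av[["vort_mag_avg"]] + 1e-14)
  }
})

test_that("hemodynamic force of a still uniform-pressure fluid is geometric", {
  ## closed boundary: the traction integral vanishes identically
  m <- mesh_rect2d(0, 0.02, -0.03, 0, 8, 8, io = "none")
  m$unit <- "m"
  n <- nrow(m$nodes)
  st <- flow_state(m, matrix(0, n, 2), rep(200, n))
  expect_lt(max(abs(hemodynamic_force(st)$force)), 1e-12)
  ## open-top box of width W: F = p0 W e_y (per unit depth)
  m2 <- mesh_rect2d(0, 0.02, -0.03, 0, 8, 8, io = "top")
  m2$unit <- "m"
  st2 <- flow_state(m2, matrix(0, n, 2), rep(200, n))
  f2 <- hemodynamic_force(st2)
  expect_equal(f2$force, c(0, 200 * 0.02), tolerance = 1e-12)
  expect_equal(f2$hdf, 4, tolerance = 1e-12)
})

test_that("traction-integral force matches the reaction-residual force on the piston", {
  fx <- fixture_piston_step()
  ft <- hemodynamic_force(fx$state)$force
  fr <- reaction_force(fx$state)
  expect_lt(sqrt(sum((ft - fr)^2)) / sqrt(sum(fr^2)), 0.01)
})

test_that("flow rate integrates plug flow exactly and vanishes at rest", {
  bc <- make_benchmark_case(phantom_spec("contracting_cylinder",
                                         n_levels = 5, n_theta = 24))
  m <- mesh_in_meters(bc$motion$mesh)
  n <- nrow(m$nodes)
  cvel <- 0.12
  st <- flow_state(m, matrix(c(0, 0, cvel), n, 3, byrow = TRUE), rep(0, n))
  bg <- lvflow:::boundary_geometry(m)
  a_io <- sum(bg$measure[bg$tag == "io"])
  expect_equal(flow_rate(st), cvel * a_io, tolerance = 1e-12)
  st0 <- flow_state(m, matrix(0, n, 3), rep(0, n))
  expect_equal(flow_rate(st0), 0)
  expect_error(flow_rate(flow_state(mesh_rect2d(0, 1, 0, 1, 2, 2, io = "none"),
                                    matrix(0, 9, 2), rep(0, 9))), "io")
})

test_that("stroke volume subtracts volumes and cross-checks the flux integral", {
  expect_equal(stroke_volume(100, 55)$sv, 45)
  expect_equal(stroke_volume(70, 70)$sv, 0)
  expect_warning(stroke_volume(50, 60), "negative")
  ## analytic flux: constant Q over systole
  t <- seq(0, 0.4, by = 0.02)
  sv <- stroke_volume(100, 55, Q = rep(45 / 0.4, length(t)), t = t,
                      systole_end = 0.4)
  expect_equal(sv$sv_flux, 45, tolerance = 1e-12)
  expect_lt(sv$discrepancy, 1e-12)
})

test_that("IO power integrates plug and parabolic profiles", {
  ## plug flow u = 0.5 m/s through A = 5 cm^2: P = 0.5 rho u^3 A = 33.1 mW
  r_eq <- sqrt(5e-4 / pi) * 1e3                   # ring radius in mm
  bc <- make_benchmark_case(phantom_spec("contracting_cylinder",
                                         radius_ed = r_eq, radius_es = r_eq,
                                         length = 4 * r_eq,
                                         n_levels = 5, n_theta = 256))
  m <- mesh_in_meters(bc$motion$mesh)
  n <- nrow(m$nodes)
  st <- flow_state(m, matrix(c(0, 0, 0.5), n, 3, byrow = TRUE), rep(0, n))
  bg <- lvflow:::boundary_geometry(m)
  a_io <- sum(bg$measure[bg$tag == "io"])
  P <- io_power(st, fluid_props())
  expect_equal(P, 0.5 * 1060 * 0.5^3 * a_io, tolerance = 1e-9)
  expect_equal(P * 1e3, 33.1, tolerance = 0.01)   # mW, at the nominal area
  ## rest state
  expect_equal(io_power(flow_state(m, matrix(0, n, 3), rep(0, n))), 0)
  ## 2D parabolic profile against a dense midpoint oracle
  H <- 0.01
  m2 <- mesh_rect2d(0, 0.03, 0, H * 1e3, 30, 40, io = "right")
  m2$nodes <- m2$nodes * 1e-3; m2$unit <- "m"
  U <- 0.5
  uex <- function(y) 4 * U * y * (H - y) / H^2
  v <- cbind(uex(m2$nodes[, 2]), 0)
  st2 <- flow_state(m2, v, rep(0, nrow(m2$nodes)))
  ys <- (seq_len(20000) - 0.5) / 20000 * H
  P_or <- mean(0.5 * 1060 * uex(ys)^2 * uex(ys)) * H
  expect_equal(io_power(st2, fluid_props()), P_or, tolerance = 0.005)
})

test_that("energetics are invariant under rigid translation of the frame", {
  fx <- fixture_piston_step()
  st <- fx$state
  st2 <- st
  st2$mesh$nodes <- sweep(st$mesh$nodes, 2, c(0.05, -0.12), "+")
  expect_equal(ke_average(st2), ke_average(st), tolerance = 1e-12)
  expect_equal(vorticity_averages(st2), vorticity_averages(st), tolerance = 1e-10)
  expect_equal(flow_rate(st2), flow_rate(st), tolerance = 1e-12)
  expect_equal(io_power(st2), io_power(st), tolerance = 1e-12)
  expect_equal(hemodynamic_force(st2)$force, hemodynamic_force(st)$force,
               tolerance = 1e-10)
})

test_that("hemodynamic series aggregates a cycle with consistent SV", {
  fx <- fixture_halfellipsoid_cycle()
  hs <- fx$series
  sv <- attr(hs, "sv")
  expect_lt(sv$discrepancy, 0.02)
  expect_identical(nrow(hs), length(fx$cyc$states))
  expect_true(all(is.finite(hs$ke_avg)))
  expect_true(all(is.finite(hs$P)))
  ## 3D cut-plane vorticity averages mirror the 2D definition
  pv <- plane_vorticity_averages(fx$cyc$states[[20]])
  expect_true(is.finite(pv[["vort_mag_avg"]]))
  expect_lte(abs(pv[["vort_avg"]]), pv[["vort_mag_avg"]] + 1e-14)
})
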