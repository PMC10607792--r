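test_that("harmonic extension reproduces trivial boundary motions", {
  m <- mesh_rect2d(0, 10, -10, 0, 6, 6, io = "top")
  wn <- boundary_nodes(m, "wall")
  ## zero boundary displacement -> zero interior displacement
  d0 <- extend_mesh_motion(m, matrix(0, length(wn), 2))
  expect_equal(max(abs(d0)), 0)
  ## uniform in-plane translation propagates everywhere (IO plane keeps
  ## its normal coordinate, so translate along x only)
  dx <- cbind(rep(0.3, length(wn)), 0)
  d1 <- extend_mesh_motion(m, dx)
  expect_equal(d1[, 1], rep(0.3, nrow(m$nodes)), tolerance = 1e-10)
  expect_equal(max(abs(d1[, 2])), 0, tolerance = 1e-10)
})

test_that("harmonic extension of a radial contraction is monotone in radius", {
  g <- phantom_motion_2d(r_ed = 20, r_es = 20)
  mot <- lumen_motion(g, n_layers = 10)
  mesh <- mot$mesh
  wn <- boundary_nodes(mesh, "wall")
  wd <- -0.1 * mesh$nodes[wn, , drop = FALSE]     # contract boundary by 10%
  wd[abs(mesh$nodes[wn, 2]) < 1e-9, 2] <- 0       # IO endpoints stay on y = 0
  d <- extend_mesh_motion(mesh, wd)
  ## along the vertical centreline, |displacement| grows with depth
  mid <- which(abs(mesh$nodes[, 1]) < 0.3)
  ord <- order(-mesh$nodes[mid, 2])               # from IO toward apex
  mag <- sqrt(rowSums(d[mid, , drop = FALSE]^2))[ord]
  expect_true(all(diff(mag) > -1e-9))
  ## inverted-element guard: reflect the boundary through the y axis
  bad <- mesh$nodes[wn, , drop = FALSE]
  bad[, 1] <- -2.2 * bad[, 1]; bad[, 2] <- 0
  expect_error(extend_mesh_motion(mesh, bad), "inverted")
})

test_that("a rigid resting lumen stays exactly at rest", {
  m <- mesh_in_meters(mesh_rect2d(0, 10, -10, 0, 5, 5, io = "top"))
  st <- flow_state(m, matrix(0, nrow(m$nodes), 2), rep(0, nrow(m$nodes)))
  for (k in 1:3) {
    st <- flow_step(st, m$nodes, fluid_props(), 0.01)
    expect_lt(max(abs(st$v)), 1e-12)
    expect_lt(max(abs(st$p)), 1e-9)
  }
})

test_that("piston box: IO flow rate equals W*s after the first step", {
  fx <- fixture_piston_step()
  Q <- flow_rate(fx$state)
  Wq <- fx$bench$spec$width * fx$bench$spec$speed * 1e-6   # mm^2/s -> m^2/s
  expect_equal(Q, Wq, tolerance = 0.01)
  expect_equal(Q, fx$bench$reference$flow_rate(0) * 1e-6, tolerance = 0.01)
})

test_that("steady Poiseuille flow is captured to 2% and converges at order ~2", {
  fx <- fixture_poiseuille()
  expect_lt(fx$rel[2], 0.02)                      # h = H/20
  expect_gte(min(fx$orders), 1.8)
})

test_that("motionless geometry yields rest states over a whole cycle", {
  g <- phantom_motion_2d(r_ed = 18, r_es = 18)
  mot <- lumen_motion(g, n_layers = 5)
  cyc <- solve_cycle(mot, n_steps = 20, n_cycles = 1)
  vmax <- max(vapply(cyc$states, function(s) max(abs(s$v)), 1))
  expect_lt(vmax, 1e-10)
  expect_lt(max(abs(cyc$diagnostics$Q)), 1e-12)
})

test_that("flux balances volume change on the sinusoidal half-ellipsoid", {
  bc <- make_benchmark_case(phantom_spec("half_ellipsoid_lv",
                                         motion_shape = "sinusoidal",
                                         n_levels = 8, n_theta = 32))
  cyc <- solve_cycle(bc$motion, n_steps = 25, n_cycles = 1)
  d <- cyc$diagnostics[-1, ]
  peak <- max(abs(d$Q))
  expect_lt(sqrt(mean((d$Q + d$dVdt)^2)) / peak, 0.01)
  ## Q(T) follows the analytic volume-rate law up to the coarse-mesh
  ## volume deficit; implicit-Euler fluxes represent step averages, so the
  ## analytic rate is evaluated at the step midpoints
  Qref <- bc$reference$flow_rate(d$T - 0.5 / 25) * 1e-9   # mm^3/s -> m^3/s
  expect_lt(sqrt(mean((d$Q - Qref)^2)) / peak, 0.06)
})

test_that("after the rest-start washout cycle, cycles repeat within 5%", {
  g <- phantom_motion_2d()
  mot <- lumen_motion(g, n_layers = 8)
  cyc <- suppressWarnings(solve_cycle(mot, n_steps = 60, n_cycles = 3))
  ke <- vapply(cyc$states, function(s) ke_average(s, cyc$props), 1)
  n <- cyc$n_steps
  peaks <- vapply(1:3, function(c) max(ke[(1 + (c - 1) * n + 1):(1 + c * n)]), 1)
  ## the first cycle starts from rest (artificial), so compare cycles 2 and 3
  expect_lt(abs(peaks[3] - peaks[2]) / peaks[2], 0.05)
  expect_lt(cyc$periodicity, 0.05)
  ## mass conservation over the whole run
  d <- cyc$diagnostics[-1, ]
  expect_lt(max(d$mass_err) / max(abs(d$Q)), 0.01)
})

test_that("kinetic energy decays monotonically in a closed resting cavity", {
  n <- 16
  m <- mesh_rect2d(0, 1, 0, 1, n, n, io = "none")
  m$unit <- "m"                                   # unit cavity in meters
  x <- m$nodes[, 1]; y <- m$nodes[, 2]
  ## divergence-free vortex vanishing on the boundary (stream function
  ## sin^2(pi x) sin^2(pi y)), scaled to a moderate Reynolds number
  amp <- 0.05
  v <- amp * cbind(2 * pi * sin(pi * x)^2 * sin(pi * y) * cos(pi * y),
                   -2 * pi * sin(pi * x) * cos(pi * x) * sin(pi * y)^2)
  st <- flow_state(m, v, rep(0, nrow(m$nodes)))
  meas <- mesh_measure(m)
  ke <- ke_average(st, fluid_props()) * meas
  for (k in 1:8) {
    st <- flow_step(st, m$nodes, fluid_props(), 0.02)
    ke2 <- ke_average(st, fluid_props()) * meas
    expect_lt(ke2, ke)
    ke <- ke2
  }
})

test_that("a uniform flow is transported exactly on a moving mesh (GCL)", {
  v0 <- c(0.3, -0.2)
  m0 <- mesh_rect2d(0, 1, 0, 1, 8, 8, io = "none")
  m0$unit <- "m"
  n <- nrow(m0$nodes)
  dt <- 0.01
  m1 <- m0
  m1$nodes <- 0.95 * m0$nodes                     # contracting mesh
  w <- (m1$nodes - m0$nodes) / dt
  bn <- boundary_nodes(m1, "wall")
  dir <- list(nodes = bn, values = matrix(v0, length(bn), 2, byrow = TRUE))
  v_old <- matrix(v0, n, 2, byrow = TRUE)
  res_c <- lvflow:::ns_solve(m1, fluid_props(), dir, dt = dt,
                             v_old = v_old, w = w)
  expect_lt(max(abs(sweep(res_c$v, 2, v0))), 1e-8)
  res_s <- lvflow:::ns_semi_step(m1, fluid_props(), dir, dt,
                                 v_old = v_old, w = w,
                                 opts = solver_options())
  expect_lt(max(abs(sweep(res_s$v, 2, v0))), 1e-8)
})

test_that("invalid stepping inputs are refused", {
  m <- mesh_in_meters(mesh_rect2d(0, 1, -1, 0, 4, 4, io = "top"))
  st <- flow_state(m, matrix(0, nrow(m$nodes), 2), rep(0, nrow(m$nodes)))
  expect_error(flow_step(st, m$nodes, fluid_props(), dt = -1), "positive")
  bad <- m$nodes; bad[13, ] <- bad[13, ] + 10     # tangle an interior node
  expect_error(flow_step(st, bad, fluid_props(), 0.01), "inverted")
  expect_error(solve_cycle(lumen_motion(phantom_motion_2d(), n_layers = 4),
                           n_steps = 10), "at least 20")
})
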