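## Shared fixtures, computed once per test session.

.lv_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .lv_cache)) assign(name, expr, envir = .lv_cache)
  get(name, envir = .lv_cache)
}

## small noisy cine phantom used across segmentation tests
fixture_small_phantom <- function() {
  cached("small_phantom",
         make_image_stack(phantom_spec("image_stack", seed = 42,
                                       n_slices = 3, n_phases = 4,
                                       rows = 96, cols = 96, r_base = 14,
                                       wall_thickness = 6)))
}

## full-size SNR-10 phantom (acceptance scale: 20 phases x 6 slices)
fixture_full_phantom <- function() {
  cached("full_phantom", make_image_stack(phantom_spec("image_stack", seed = 11)))
}

fixture_full_segmentation <- function() {
  cached("full_segmentation", {
    ph <- fixture_full_phantom()
    segment_cine_stack(ph$images, center_hint = ph$center_px)
  })
}

## one advanced piston step (criterion benchmarks + HDF cross-check)
fixture_piston_step <- function() {
  cached("piston_step", {
    bench <- make_benchmark_case(phantom_spec("piston_box"))
    mesh <- mesh_in_meters(bench$motion$mesh)
    dt <- 0.01
    newpos <- bench$motion$wall_pos(dt / bench$spec$duration) * 1e-3
    nodes2 <- mesh$nodes
    wn <- bench$motion$wall_nodes
    nodes2[wn, ] <- newpos
    ## interior follows the same vertical stretch law (affine, harmonic)
    fac <- (bench$spec$height - bench$spec$speed * dt) / bench$spec$height
    nodes2 <- cbind(mesh$nodes[, 1], mesh$nodes[, 2] * fac)
    st0 <- flow_state(mesh, matrix(0, nrow(mesh$nodes), 2),
                      rep(0, nrow(mesh$nodes)))
    st <- flow_step(st0, nodes2, fluid_props(), dt)
    list(bench = bench, state = st, dt = dt)
  })
}

## coarse half-ellipsoid LV cycle (reference motion: a 80 -> 64 mm,
## b = 25 mm, 40% systole); shared by mass-conservation and recovery tests
fixture_halfellipsoid_cycle <- function() {
  cached("halfellipsoid_cycle", {
    bench <- make_benchmark_case(phantom_spec("half_ellipsoid_lv"))
    cyc <- solve_cycle(bench$motion, n_steps = 40, n_cycles = 1)
    list(bench = bench, cyc = cyc, series = hemo_series(cyc))
  })
}

## steady Poiseuille channel solve at a given wall resolution
poiseuille_error <- function(ncell_h) {
  H <- 10; L <- 30
  m <- mesh_rect2d(0, L, 0, H, nx = 3 * ncell_h, ny = ncell_h, io = "right",
                   tags = list(left = "inflow"))
  m <- mesh_in_meters(m)
  Hm <- H * 1e-3
  U <- 0.004                                       # Re ~ 10
  uex <- function(y) 4 * U * y * (Hm - y) / Hm^2
  wn <- boundary_nodes(m, c("wall", "inflow"))
  vals <- matrix(0, length(wn), 2)
  infl <- abs(m$nodes[wn, 1]) < 1e-12
  vals[infl, 1] <- uex(m$nodes[wn[infl], 2])
  res <- lvflow:::ns_solve(m, fluid_props(), list(nodes = wn, values = vals),
                           steady = TRUE)
  M <- lvflow:::assemble_fem(m)$M
  err <- res$v[, 1] - uex(m$nodes[, 2])
  ue <- uex(m$nodes[, 2])
  sqrt(as.numeric(t(err) %*% M %*% err)) / sqrt(as.numeric(t(ue) %*% M %*% ue))
}

fixture_poiseuille <- function() {
  cached("poiseuille", {
    rels <- vapply(c(10, 20, 40), poiseuille_error, 1)
    list(rel = rels, orders = diff(log(rels)) / log(0.5))
  })
}

## analytic-field helpers
rect_state <- function(nx = 20, ny = 20, vfun, pfun = NULL, io = "none",
                       x0 = 0, x1 = 1, y0 = 0, y1 = 1, unit_m = TRUE) {
  m <- mesh_rect2d(x0, x1, y0, y1, nx, ny, io = io)
  m$unit <- "m"                                    # treat coordinates as meters
  v <- t(apply(m$nodes, 1, vfun))
  p <- if (is.null(pfun)) rep(0, nrow(m$nodes)) else apply(m$nodes, 1, pfun)
  flow_state(m, v, p)
}
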