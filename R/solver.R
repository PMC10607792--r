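## Incompressible Newtonian flow in the moving LV lumen.
##
## Discretization: equal-order linear velocity/pressure (P1/Q1) with
## Brezzi-Pitkaranta/PSPG-type pressure stabilization; implicit (backward
## Euler) time stepping in an arbitrary Lagrangian-Eulerian (ALE) frame.
## Nodal values travel with the mesh, so the discrete time derivative is the
## ALE derivative and convection uses the relative velocity v - w (w = mesh
## velocity). The wall carries the imposed kinematic velocity from the imaged
## motion; the IO boundary carries the natural "do-nothing" zero-traction
## condition (mu dv/dn - p n = 0), which also sets the pressure gauge (p is
## relative to the IO). All internal computation is in SI units (m, s, Pa).

#' Blood properties
#'
#' Defaults: dynamic viscosity 4 cP (4e-3 Pa s) and density 1060 kg/m^3,
#' the standard Newtonian blood assumption.
#'
#' @param mu dynamic viscosity, Pa s.
#' @param rho density, kg/m^3.
#' @return object of class `lv_fluid`.
#' @export
fluid_props <- function(mu = 4e-3, rho = 1060) {
  if (mu <= 0 || rho <= 0) stopf("viscosity and density must be positive")
  structure(list(mu = mu, rho = rho), class = "lv_fluid")
}

#' @export
print.lv_fluid <- function(x, ...) {
  cat(sprintf("<lv_fluid> mu = %g Pa.s, rho = %g kg/m^3\n", x$mu, x$rho))
  invisible(x)
}

#' Flow-solver options
#'
#' @param scheme transient time-stepping scheme. "coupled": fully implicit
#'   with Picard iteration on the convection (always used for steady solves).
#'   "semi_implicit": implicit viscous/pressure with the convective term
#'   evaluated at the old time level, solved by a Cholesky/Schur-complement
#'   method; much faster but requires convective CFL of order one. "auto"
#'   (default): coupled in 2D (small systems, and the collapsed corner cells
#'   of the transfinite lumen mesh carry large local CFL), semi-implicit in
#'   3D (structured meshes with moderate CFL).
#' @param picard_tol,max_picard nonlinear iteration control (coupled scheme).
#' @param cg_tol relative tolerance of the pressure Schur-complement CG.
#' @param stab_alpha pressure-stabilization scaling (1 = standard).
#' @param backflow enable backflow stabilization on the IO boundary
#'   (off by default, matching the plain zero-traction condition).
#' @param cfl_warn advisory convective CFL threshold.
#' @return list of options for [flow_step()] / [solve_cycle()].
#' @export
solver_options <- function(scheme = c("auto", "semi_implicit", "coupled"),
                           picard_tol = 1e-7, max_picard = 30, cg_tol = 1e-12,
                           stab_alpha = 1, backflow = FALSE, cfl_warn = 5) {
  list(scheme = match.arg(scheme), picard_tol = picard_tol,
       max_picard = max_picard, cg_tol = cg_tol,
       stab_alpha = stab_alpha, backflow = backflow, cfl_warn = cfl_warn)
}

## One semi-implicit ALE step: viscous + pressure implicit, convection
## evaluated with the old velocity (relative to the mesh). The velocity block
## is SPD and shared by all components, so the step reduces to Cholesky
## backsolves plus a preconditioned CG on the pressure Schur complement.
ns_semi_step <- function(mesh, props, dirichlet, dt, v_old, w, opts) {
  n <- nrow(mesh$nodes); d <- mesh$dim
  rho <- props$rho; mu <- props$mu
  a <- v_old - w
  h <- element_sizes(mesh)
  delta <- stab_delta(opts, props, h, element_speed(mesh, a), dt)
  fm <- assemble_fem(mesh, a = a, delta = delta)
  Auu <- (rho / dt) * fm$M + mu * fm$K
  has_io <- any(mesh$btag == "io")
  if (isTRUE(opts$backflow) && has_io) {
    bg <- boundary_geometry(mesh)
    nn <- matrix(0, n, d)
    sel <- which(bg$tag == "io")
    for (f in sel) for (v in bg$faces[f, ]) nn[v, ] <- nn[v, ] + bg$normal[f, ]
    nrm <- sqrt(rowSums(nn^2)); nz <- nrm > 0
    nn[nz, ] <- nn[nz, ] / nrm[nz]
    beta <- pmax(0, -rowSums(v_old * nn)) * rho / 2
    Auu <- Auu + boundary_weighted_mass(mesh, bg, beta, "io")
  }
  Dl <- lapply(seq_len(d), function(k) fm[[paste0("D", k)]])
  fmat <- (rho / dt) * (fm$M %*% v_old) - rho * (fm$C %*% v_old)
  cons <- dirichlet$nodes
  vals <- as.matrix(dirichlet$values)
  free <- setdiff(seq_len(n), cons)
  Ch <- Matrix::Cholesky(Matrix::forceSymmetric(Auu[free, free, drop = FALSE]),
                         LDL = FALSE, perm = TRUE)
  Afc <- Auu[free, cons, drop = FALSE]
  E <- lapply(Dl, function(D) D[, free, drop = FALSE])
  Dc <- lapply(Dl, function(D) D[, cons, drop = FALSE])
  y <- vector("list", d)
  rhs_p <- numeric(n)
  for (k in seq_len(d)) {
    g <- as.numeric(fmat[free, k]) - as.numeric(Afc %*% vals[, k])
    y[[k]] <- as.numeric(Matrix::solve(Ch, g))
    rhs_p <- rhs_p - as.numeric(E[[k]] %*% y[[k]]) - as.numeric(Dc[[k]] %*% vals[, k])
  }
  apply_schur <- function(p) {
    out <- as.numeric(fm$S %*% p)
    for (k in seq_len(d)) {
      t1 <- as.numeric(Matrix::crossprod(E[[k]], p))
      out <- out + as.numeric(E[[k]] %*% as.numeric(Matrix::solve(Ch, t1)))
    }
    out
  }
  ## preconditioner: (dt/rho) * pressure Laplacian + stabilization
  Ms <- (dt / rho) * fm$K + fm$S
  Ms <- Ms + Matrix::Diagonal(n, x = rep(1e-10 * max(abs(Matrix::diag(Ms))), n))
  Chp <- Matrix::Cholesky(Matrix::forceSymmetric(Ms), LDL = FALSE, perm = TRUE)
  deflate <- !has_io                              # enclosed flow: p up to const
  pcg <- function(rhs) {
    if (deflate) rhs <- rhs - mean(rhs)
    p <- numeric(n)
    r <- rhs
    z <- as.numeric(Matrix::solve(Chp, r)); if (deflate) z <- z - mean(z)
    q <- z
    rz <- sum(r * z)
    nrm0 <- sqrt(sum(rhs^2))
    if (nrm0 == 0) return(p)
    for (it in seq_len(400)) {
      Sq <- apply_schur(q); if (deflate) Sq <- Sq - mean(Sq)
      alpha <- rz / sum(q * Sq)
      p <- p + alpha * q
      r <- r - alpha * Sq
      if (sqrt(sum(r^2)) <= opts$cg_tol * nrm0) return(p)
      z <- as.numeric(Matrix::solve(Chp, r)); if (deflate) z <- z - mean(z)
      rz2 <- sum(r * z)
      q <- z + (rz2 / rz) * q
      rz <- rz2
    }
    stopf("pressure CG did not converge (residual %.3g of initial)",
          sqrt(sum(r^2)) / nrm0)
  }
  p <- pcg(rhs_p)
  v <- matrix(0, n, d)
  for (k in seq_len(d)) {
    t1 <- as.numeric(Matrix::crossprod(E[[k]], p))
    v[free, k] <- y[[k]] + as.numeric(Matrix::solve(Ch, t1))
    v[cons, k] <- vals[, k]
  }
  reaction <- matrix(0, n, d)
  for (k in seq_len(d))
    reaction[, k] <- as.numeric(Auu %*% v[, k]) -
      as.numeric(Matrix::t(Dl[[k]]) %*% p) - as.numeric(fmat[, k])
  list(v = v, p = p, reaction = reaction, picard_iters = 1L, rel_change = NA_real_)
}

#' Harmonic extension of boundary motion into the mesh interior
#'
#' Solves a Laplace problem per displacement component with the prescribed
#' displacement on the wall; IO-plane nodes are constrained to stay in the IO
#' plane (zero displacement along the IO normal axis) but slide freely within
#' it. Errors if the displaced mesh contains inverted elements.
#'
#' @param mesh reference `lv_mesh` with "wall"/"io" boundary tags.
#' @param wall_disp matrix `length(wall_nodes) x dim` of displacements for
#'   `boundary_nodes(mesh, "wall")` (in mesh units), or a full `n x dim`
#'   matrix whose wall rows are used.
#' @param io_axis index of the coordinate axis normal to the IO plane
#'   (default: 2 in 2D, 3 in 3D).
#' @return `n x dim` nodal displacement matrix.
#' @export
extend_mesh_motion <- function(mesh, wall_disp, io_axis = mesh$dim) {
  n <- nrow(mesh$nodes); d <- mesh$dim
  wn <- boundary_nodes(mesh, "wall")
  io <- setdiff(boundary_nodes(mesh, "io"), wn)
  wall_disp <- as.matrix(wall_disp)
  if (nrow(wall_disp) == n) wall_disp <- wall_disp[wn, , drop = FALSE]
  if (nrow(wall_disp) != length(wn))
    stopf("wall_disp must have one row per wall node (%d), got %d",
          length(wn), nrow(wall_disp))
  K <- assemble_fem(mesh)$K
  disp <- matrix(0, n, d)
  for (k in seq_len(d)) {
    fixed <- wn; vals <- wall_disp[, k]
    if (k == io_axis && length(io)) { fixed <- c(fixed, io); vals <- c(vals, rep(0, length(io))) }
    free <- setdiff(seq_len(n), fixed)
    rhs <- -K[free, fixed, drop = FALSE] %*% vals
    disp[fixed, k] <- vals
    if (length(free)) {
      Kff <- methods::as(K[free, free, drop = FALSE], "symmetricMatrix")
      disp[free, k] <- as.numeric(Matrix::solve(Matrix::Cholesky(Kff, LDL = FALSE), rhs))
    }
  }
  m2 <- mesh; m2$nodes <- mesh$nodes + disp
  if (mesh_quality(m2)$min_jacobian <= 0)
    stopf("harmonic mesh extension produced inverted elements; remesh or use a smaller step")
  disp
}

## Factorized harmonic extender for repeated calls on one reference mesh.
make_extender <- function(mesh, io_axis = mesh$dim) {
  n <- nrow(mesh$nodes); d <- mesh$dim
  wn <- boundary_nodes(mesh, "wall")
  io <- setdiff(boundary_nodes(mesh, "io"), wn)
  K <- assemble_fem(mesh)$K
  per_k <- lapply(seq_len(d), function(k) {
    fixed <- if (k == io_axis && length(io)) c(wn, io) else wn
    free <- setdiff(seq_len(n), fixed)
    Kff <- methods::as(K[free, free, drop = FALSE], "symmetricMatrix")
    list(fixed = fixed, free = free, Kfc = K[free, fixed, drop = FALSE],
         fac = Matrix::Cholesky(Kff, LDL = FALSE))
  })
  function(wall_disp) {
    disp <- matrix(0, n, d)
    for (k in seq_len(d)) {
      pk <- per_k[[k]]
      vals <- if (k == io_axis && length(io)) c(wall_disp[, k], rep(0, length(io)))
              else wall_disp[, k]
      disp[pk$fixed, k] <- vals
      if (length(pk$free))
        disp[pk$free, k] <- as.numeric(Matrix::solve(pk$fac, -pk$Kfc %*% vals))
    }
    disp
  }
}

## PSPG-type stabilization weight per element.
stab_delta <- function(opts, props, h, aspeed, dt) {
  nu <- props$mu / props$rho
  inv_t <- if (is.finite(dt)) (2 / dt)^2 else 0
  tau <- 1 / sqrt(inv_t + (2 * aspeed / h)^2 + (12 * nu / h^2)^2)
  opts$stab_alpha * tau / props$rho
}

## Core mixed solve: one backward-Euler step (or a steady solve) of
## incompressible Navier-Stokes on a fixed current-configuration mesh.
##   mesh      lv_mesh in meters
##   v_old     n x d velocity at previous time level (ignored if steady)
##   w         n x d mesh velocity (ALE), zero for fixed mesh
##   dirichlet list(nodes = idx, values = matrix length(idx) x d)
##   dt        time step (s); Inf or NULL with steady = TRUE
## Returns list(v, p, reaction, picard_iters, rel_change).
ns_solve <- function(mesh, props, dirichlet, dt = NULL, v_old = NULL, w = NULL,
                     steady = is.null(dt), v_init = NULL, opts = solver_options()) {
  stopifnot(mesh$unit == "m")
  n <- nrow(mesh$nodes); d <- mesh$dim
  if (is.null(w)) w <- matrix(0, n, d)
  if (is.null(v_old)) v_old <- matrix(0, n, d)
  v_iter <- if (!is.null(v_init)) v_init else v_old
  h <- element_sizes(mesh)
  has_io <- any(mesh$btag == "io")
  bg <- if (has_io || isTRUE(opts$backflow)) boundary_geometry(mesh)
  cons_nodes <- dirichlet$nodes
  cons_vals <- as.matrix(dirichlet$values)
  vd <- as.vector(outer(cons_nodes, (seq_len(d) - 1L) * n, "+"))
  pin_p <- !has_io
  rel <- Inf; it <- 0
  A0 <- NULL; b0 <- NULL; sol <- NULL
  rho <- props$rho; mu <- props$mu
  while (it < opts$max_picard && rel > opts$picard_tol) {
    it <- it + 1
    a <- v_iter - w
    delta <- stab_delta(opts, props, h, element_speed(mesh, a),
                        if (steady) Inf else dt)
    fm <- assemble_fem(mesh, a = a, delta = delta)
    Auu <- mu * fm$K + rho * fm$C
    if (!steady) Auu <- Auu + (rho / dt) * fm$M
    if (isTRUE(opts$backflow) && has_io) {
      ## nodal IO normal: face normals averaged at nodes
      nn <- matrix(0, n, d)
      sel <- which(bg$tag == "io")
      for (f in sel) for (v in bg$faces[f, ]) nn[v, ] <- nn[v, ] + bg$normal[f, ]
      nrm <- sqrt(rowSums(nn^2)); nz <- nrm > 0
      nn[nz, ] <- nn[nz, ] / nrm[nz]
      beta <- pmax(0, -rowSums(v_iter * nn)) * rho / 2
      Auu <- Auu + boundary_weighted_mass(mesh, bg, beta, "io")
    }
    Dl <- lapply(seq_len(d), function(k) fm[[paste0("D", k)]])
    blocks <- vector("list", (d + 1)^2)
    dim(blocks) <- c(d + 1, d + 1)
    zero <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(), dims = c(n, n))
    for (i in seq_len(d)) for (j in seq_len(d)) blocks[[i, j]] <- if (i == j) Auu else zero
    for (i in seq_len(d)) { blocks[[i, d + 1]] <- -Matrix::t(Dl[[i]]); blocks[[d + 1, i]] <- Dl[[i]] }
    blocks[[d + 1, d + 1]] <- fm$S
    A <- do.call(rbind, lapply(seq_len(d + 1), function(i)
      do.call(cbind, blocks[i, ])))
    b <- numeric((d + 1) * n)
    if (!steady) {
      Mv <- (rho / dt) * (fm$M %*% v_old)
      for (k in seq_len(d)) b[(k - 1) * n + seq_len(n)] <- Mv[, k]
    }
    A0 <- A; b0 <- b
    ## Dirichlet velocity rows
    keep <- rep(1, (d + 1) * n); keep[vd] <- 0
    if (pin_p) keep[d * n + 1L] <- 0
    A <- Matrix::Diagonal(x = keep) %*% A
    ones <- if (pin_p) c(vd, d * n + 1L) else vd
    A <- A + Matrix::sparseMatrix(i = ones, j = ones, x = rep(1, length(ones)),
                                  dims = dim(A))
    b[vd] <- as.vector(cons_vals)
    if (pin_p) b[d * n + 1L] <- 0
    sol <- as.numeric(Matrix::solve(Matrix::lu(A), b))
    v_new <- matrix(sol[seq_len(d * n)], n, d)
    denom <- max(sqrt(sum(v_new^2)), 1e-300)
    rel <- sqrt(sum((v_new - v_iter)^2)) / denom
    v_iter <- v_new
  }
  if (rel > max(opts$picard_tol, 1e-4) && it >= opts$max_picard)
    stopf("nonlinear iteration did not converge (rel change %.3g after %d iterations)", rel, it)
  v <- v_iter
  p <- sol[d * n + seq_len(n)]
  resid <- as.numeric(A0 %*% sol - b0)
  reaction <- matrix(resid[seq_len(d * n)], n, d)
  list(v = v, p = p, reaction = reaction, picard_iters = it, rel_change = rel)
}

#' One ALE time step of the lumen flow
#'
#' Advances a flow state by `dt` while the mesh moves from its current node
#' positions to `new_nodes` (same connectivity). The wall receives the
#' kinematic no-slip velocity (node displacement / dt); the IO boundary keeps
#' the zero-traction condition.
#'
#' @param state a `lv_flow_state` (see [flow_state()]).
#' @param new_nodes node positions at the end of the step, meters.
#' @param props [fluid_props()].
#' @param dt time step, s.
#' @param opts solver options, see `solver_options()`.
#' @return the advanced `lv_flow_state`.
#' @export
flow_step <- function(state, new_nodes, props, dt, opts = solver_options()) {
  if (dt <= 0) stopf("dt must be positive")
  mesh <- state$mesh
  w <- (new_nodes - mesh$nodes) / dt
  mesh$nodes <- new_nodes
  if (mesh_quality(mesh)$min_jacobian <= 0)
    stopf("mesh motion inverted an element at t = %g s", state$t + dt)
  wn <- boundary_nodes(mesh, "wall")
  dirichlet <- list(nodes = wn, values = w[wn, , drop = FALSE])
  scheme <- opts$scheme %||% "auto"
  if (scheme == "auto") scheme <- if (mesh$dim == 3) "semi_implicit" else "coupled"
  res <- if (scheme == "semi_implicit")
    ns_semi_step(mesh, props, dirichlet, dt, v_old = state$v, w = w, opts = opts)
  else
    ns_solve(mesh, props, dirichlet, dt = dt, v_old = state$v, w = w,
             v_init = state$v, opts = opts)
  ## convective CFL advisory
  h <- element_sizes(mesh)
  cfl <- max(element_speed(mesh, res$v - w) * dt / h)
  if (is.finite(opts$cfl_warn) && cfl > opts$cfl_warn)
    warnf("convective CFL = %.2f exceeds %g (implicit stepping tolerates this)", cfl, opts$cfl_warn)
  flow_state(mesh, res$v, res$p, w = w, t = state$t + dt,
             phase = NA_real_, reaction = res$reaction,
             picard_iters = res$picard_iters, cfl = cfl)
}

#' Construct a flow state
#'
#' @param mesh current-configuration `lv_mesh` (meters).
#' @param v nodal velocity, m/s.
#' @param p nodal pressure relative to the IO boundary, Pa.
#' @param w nodal mesh (ALE) velocity, m/s.
#' @param t physical time, s.
#' @param phase normalized cycle time in [0, 1].
#' @param reaction,picard_iters,cfl solver diagnostics (optional).
#' @return object of class `lv_flow_state`.
#' @export
flow_state <- function(mesh, v, p, w = NULL, t = 0, phase = NA_real_,
                       reaction = NULL, picard_iters = NA_integer_, cfl = NA_real_) {
  n <- nrow(mesh$nodes)
  if (is.null(w)) w <- matrix(0, n, mesh$dim)
  structure(list(mesh = mesh, v = v, p = p, w = w, t = t, phase = phase,
                 reaction = reaction, picard_iters = picard_iters, cfl = cfl),
            class = "lv_flow_state")
}

#' @export
print.lv_flow_state <- function(x, ...) {
  cat(sprintf("<lv_flow_state> t = %.4g s (T = %.3g), %d nodes, max |v| = %.4g m/s\n",
              x$t, x$phase, nrow(x$mesh$nodes), sqrt(max(rowSums(x$v^2)))))
  invisible(x)
}

#' Simulate the full cardiac cycle in the moving lumen
#'
#' Marches backward-Euler steps over `n_cycles` heart beats starting from
#' rest at end diastole. Boundary motion comes from a lumen motion object
#' (see [lumen_motion()]); interior mesh motion is the harmonic extension of
#' the wall displacement computed on the end-diastolic reference mesh.
#'
#' @param motion a `lv_lumen_motion` object.
#' @param props [fluid_props()].
#' @param n_steps time steps per cycle (>= 20; default 200).
#' @param n_cycles number of cycles simulated (default 2; the first washes
#'   out the artificial rest initial condition).
#' @param store "all" to keep every state, "last_cycle" to keep only the
#'   final cycle (diagnostics always cover every step).
#' @param opts solver options, see `solver_options()`.
#' @return object of class `lv_cycle`: list of states, per-step diagnostics
#'   data frame, and the cycle-periodicity L2 diagnostic.
#' @export
solve_cycle <- function(motion, props = fluid_props(), n_steps = 200,
                        n_cycles = 2, store = c("all", "last_cycle"),
                        opts = solver_options()) {
  store <- match.arg(store)
  if (n_steps < 20) stopf("need at least 20 steps per cycle")
  mesh0 <- mesh_in_meters(motion$mesh)
  wn <- motion$wall_nodes
  cycle_s <- 60 / motion$cycle$heart_rate
  dt <- cycle_s / n_steps
  extender <- make_extender(mesh0)
  pos_at <- function(T) {
    wp <- motion$wall_pos(T) * 1e-3                # mm -> m
    disp_w <- wp - mesh0$nodes[wn, , drop = FALSE]
    mesh0$nodes + extender(disp_w)
  }
  total <- n_steps * n_cycles
  states <- vector("list", total + 1)
  mesh0$bowner <- boundary_geometry(mesh0)$owner   # connectivity is fixed
  mesh_ed <- mesh0
  mesh_ed$nodes <- pos_at(0)
  state <- flow_state(mesh_ed,
                      v = matrix(0, nrow(mesh0$nodes), mesh0$dim),
                      p = rep(0, nrow(mesh0$nodes)), t = 0, phase = 0)
  states[[1]] <- state
  diag_rows <- vector("list", total + 1)
  owner_cache <- NULL
  measure0 <- mesh_measure(state$mesh)
  diag_rows[[1]] <- data.frame(step = 0L, t = 0, T = 0, V = measure0, Q = 0,
                               cfl = 0, picard = 0L)
  prevV <- measure0
  cycle_end_v <- list()
  for (s in seq_len(total)) {
    Tn <- (s %% n_steps) / n_steps
    if (Tn == 0) Tn <- 1
    newpos <- pos_at(Tn)
    st <- flow_step(state, newpos, props, dt, opts = opts)
    st$phase <- Tn
    bg <- boundary_geometry(st$mesh)
    Q <- face_flux(st$mesh, bg, st$v, "io")
    V <- mesh_measure(st$mesh)
    diag_rows[[s + 1]] <- data.frame(step = s, t = st$t, T = Tn, V = V, Q = Q,
                                     cfl = st$cfl, picard = st$picard_iters)
    prevV <- V
    state <- st
    states[[s + 1]] <- st
    if (s %% n_steps == 0) cycle_end_v <- c(cycle_end_v, list(st$v))
  }
  diagnostics <- do.call(rbind, diag_rows)
  ## mass balance: Q vs backward-difference volume rate, relative to peak |Q|
  dVdt <- c(NA, diff(diagnostics$V) / dt)
  diagnostics$dVdt <- dVdt
  diagnostics$mass_err <- abs(diagnostics$Q + dVdt)
  periodicity <- NA_real_
  if (length(cycle_end_v) >= 2) {
    k <- length(cycle_end_v)
    a <- cycle_end_v[[k]]; b <- cycle_end_v[[k - 1]]
    periodicity <- sqrt(sum((a - b)^2)) / max(sqrt(sum(a^2)), 1e-300)
  }
  if (store == "last_cycle") states <- states[(total - n_steps + 1):(total + 1)]
  structure(list(states = states, diagnostics = diagnostics,
                 periodicity = periodicity, n_steps = n_steps,
                 n_cycles = n_cycles, dt = dt, props = props, motion = motion),
            class = "lv_cycle")
}

#' @export
print.lv_cycle <- function(x, ...) {
  d <- x$diagnostics
  peakQ <- max(abs(d$Q))
  merr <- max(d$mass_err[-1] / max(peakQ, 1e-300))
  cat(sprintf("<lv_cycle> %d cycle(s) x %d steps, dt = %.4g s\n",
              x$n_cycles, x$n_steps, x$dt))
  cat(sprintf("  peak |Q| = %.4g m^%d/s, max mass-balance error = %.3g of peak\n",
              peakQ, x$states[[1]]$mesh$dim, merr))
  cat(sprintf("  cycle periodicity (rel L2 of v) = %.3g\n", x$periodicity))
  invisible(x)
}
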