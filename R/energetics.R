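## Hemodynamic quantities derived from flow states: kinetic-energy density
## and spatial averages, vorticity fields and averages, hemodynamic force,
## IO flow rate, stroke volume and IO kinetic-energy power.
##
## All operators work on the solver's SI fields (m, m/s, Pa); series
## assembled by hemo_series() convert to reporting units (mm^2 or mL, mL/s,
## J/m^3, 1/s, N or N per metre depth, mW).

#' Kinetic-energy density of a flow state
#'
#' Pointwise \eqn{KE = \tfrac12 \rho \lVert v\rVert^2} at the mesh nodes.
#'
#' @param state `lv_flow_state`.
#' @param props [fluid_props()].
#' @return nodal vector, J/m^3.
#' @export
ke_density <- function(state, props = fluid_props()) {
  0.5 * props$rho * rowSums(state$v^2)
}

#' Spatial average of the kinetic-energy density
#'
#' \eqn{(1/A)\int KE\,dA} (2D) or the volume analogue (3D), integrated
#' exactly for the linear velocity interpolation via the consistent mass
#' matrix.
#'
#' @param state `lv_flow_state`.
#' @param props [fluid_props()].
#' @return J/m^3.
#' @export
ke_average <- function(state, props = fluid_props()) {
  meas <- mesh_measure(state$mesh)
  if (meas <= 0) stopf("zero-measure domain")
  M <- assemble_fem(state$mesh)$M
  en <- 0
  for (k in seq_len(state$mesh$dim))
    en <- en + as.numeric(t(state$v[, k]) %*% M %*% state$v[, k])
  0.5 * props$rho * en / meas
}

## per-element velocity gradients: list of m x d x d arrays (dv_i/dx_j),
## canonical element order tri, quad, tet; quads evaluated at the centre.
element_velocity_gradients <- function(mesh, v) {
  out <- list(); meas <- numeric(0)
  if (nrow(mesh$tri)) {
    gd <- tri_gradients(mesh$nodes, mesh$tri)
    g <- array(0, c(nrow(mesh$tri), 2, 2))
    for (i in 1:2) for (j in 1:2)
      g[, i, j] <- rowSums(matrix(v[mesh$tri, i], ncol = 3) * gd$g[, , j])
    out$tri <- g; meas <- c(meas, gd$measure)
  }
  if (nrow(mesh$quad)) {
    q <- mesh$quad; m <- nrow(q)
    xs <- matrix(mesh$nodes[q, 1], ncol = 4); ys <- matrix(mesh$nodes[q, 2], ncol = 4)
    sh <- q1_shape(0, 0)
    j11 <- xs %*% sh$dN[, 1]; j21 <- ys %*% sh$dN[, 1]
    j12 <- xs %*% sh$dN[, 2]; j22 <- ys %*% sh$dN[, 2]
    detJ <- as.numeric(j11 * j22 - j12 * j21)
    gx <- matrix(0, m, 4); gy <- matrix(0, m, 4)
    for (i in 1:4) {
      gx[, i] <- ( j22 * sh$dN[i, 1] - j21 * sh$dN[i, 2]) / detJ
      gy[, i] <- (-j12 * sh$dN[i, 1] + j11 * sh$dN[i, 2]) / detJ
    }
    g <- array(0, c(m, 2, 2))
    for (i in 1:2) {
      vi <- matrix(v[q, i], ncol = 4)
      g[, i, 1] <- rowSums(vi * gx); g[, i, 2] <- rowSums(vi * gy)
    }
    cj <- quad_corner_jacobians(mesh$nodes, q)
    out$quad <- g; meas <- c(meas, rowSums(cj) / 4)
  }
  if (nrow(mesh$tet)) {
    gd <- tet_gradients(mesh$nodes, mesh$tet)
    g <- array(0, c(nrow(mesh$tet), 3, 3))
    for (i in 1:3) for (j in 1:3)
      g[, i, j] <- rowSums(matrix(v[mesh$tet, i], ncol = 4) * gd$g[, , j])
    out$tet <- g; meas <- c(meas, gd$measure)
  }
  list(grad = out, measure = meas)
}

#' Vorticity of a flow state
#'
#' \eqn{\Omega = \nabla \times v} from the discretization's consistent
#' gradients, element by element. In 2D the out-of-plane scalar
#' \eqn{\Omega_z} is returned; in 3D the vorticity vector. Exact for affine
#' velocity fields.
#'
#' @param state `lv_flow_state`.
#' @return list with `elem` (per-element values, scalar in 2D, m x 3 in 3D)
#'   and `measure` (element areas/volumes), canonical element order.
#' @export
vorticity <- function(state) {
  eg <- element_velocity_gradients(state$mesh, state$v)
  gs <- eg$grad
  if (state$mesh$dim == 2) {
    om <- unlist(lapply(gs, function(g) g[, 2, 1] - g[, 1, 2]), use.names = FALSE)
  } else {
    g <- gs$tet
    om <- cbind(g[, 3, 2] - g[, 2, 3], g[, 1, 3] - g[, 3, 1], g[, 2, 1] - g[, 1, 2])
  }
  list(elem = om, measure = eg$measure)
}

#' Vorticity magnitude average and signed vorticity average
#'
#' 2D: \eqn{\bar{\lVert\Omega\rVert} = (1/A)\int |\Omega_z|\,dA} (rotational
#' intensity) and \eqn{\bar\Omega = (1/A)\int \Omega_z\,dA} (rotational
#' balance; zero for mirror-symmetric flow). 3D: the same pair computed from
#' the vorticity component normal to a long-axis cut plane is available via
#' [plane_vorticity_averages()]; here the volume-averaged vorticity
#' magnitude \eqn{(1/V)\int \lVert\Omega\rVert\,dV} is reported as
#' `vort_mag_avg` with `vort_avg = NA`.
#'
#' @param state `lv_flow_state`.
#' @return named vector `c(vort_mag_avg, vort_avg)`, 1/s.
#' @export
vorticity_averages <- function(state) {
  vo <- vorticity(state)
  meas <- sum(vo$measure)
  if (meas <= 0) stopf("zero-measure domain")
  if (state$mesh$dim == 2) {
    c(vort_mag_avg = sum(abs(vo$elem) * vo$measure) / meas,
      vort_avg = sum(vo$elem * vo$measure) / meas)
  } else {
    mag <- sqrt(rowSums(vo$elem^2))
    c(vort_mag_avg = sum(mag * vo$measure) / meas, vort_avg = NA_real_)
  }
}

#' Vorticity averages on a long-axis cut plane (3D states)
#'
#' Samples the cut plane `{y = value}` (normal e_y, containing the long
#' axis) on a uniform grid, keeps points inside the lumen, and averages the
#' plane-normal vorticity component, mirroring the 2D definitions.
#'
#' @param state 3D `lv_flow_state`.
#' @param value plane offset along y, meters (default 0: through the axis).
#' @param n_grid grid resolution per direction.
#' @return named vector `c(vort_mag_avg, vort_avg)` over the cut plane, 1/s.
#' @export
plane_vorticity_averages <- function(state, value = 0, n_grid = 40) {
  mesh <- state$mesh
  if (mesh$dim != 3) stopf("cut-plane averages are for 3D states")
  vo <- vorticity(state)
  tet <- mesh$tet; nd <- mesh$nodes
  ## tets crossed by the plane y = value
  ymin <- apply(matrix(nd[tet, 2], ncol = 4), 1, min)
  ymax <- apply(matrix(nd[tet, 2], ncol = 4), 1, max)
  sel <- which(ymin <= value & ymax >= value)
  if (!length(sel)) stopf("cut plane does not intersect the lumen")
  ## weight by an area proxy: V_K / y-extent of the tet
  w <- vo$measure[sel] / pmax(ymax[sel] - ymin[sel], 1e-300)
  omn <- vo$elem[sel, 2]
  c(vort_mag_avg = sum(abs(omn) * w) / sum(w),
    vort_avg = sum(omn * w) / sum(w))
}

#' Hemodynamic force on the lumen wall
#'
#' Traction integral \eqn{F = \oint_S \sigma \cdot n\, dS} over the wall
#' (IO excluded), with the full Newtonian stress
#' \eqn{\sigma = -p I + \mu(\nabla v + \nabla v^T)} and n outward from the
#' fluid: the total force exchanged between blood and wall. For a still
#' fluid at uniform pressure p0 in an open-top 2D box of IO width W this
#' evaluates to +p0 W along +y. The HDF scalar is the "vertical"
#' (base-to-apex axis) component: +y in 2D, +z in 3D, positive toward the
#' base. 2D results are per unit out-of-plane depth.
#'
#' @param state `lv_flow_state`.
#' @param props [fluid_props()].
#' @return list `force` (length-d vector, N or N/m) and `hdf` (scalar).
#' @export
hemodynamic_force <- function(state, props = fluid_props()) {
  mesh <- state$mesh
  d <- mesh$dim
  bg <- boundary_geometry(mesh)
  sel <- which(bg$tag == "wall")
  if (!length(sel)) stopf("mesh has no wall-tagged boundary")
  eg <- element_velocity_gradients(mesh, state$v)
  grads <- rbind_grad(eg$grad, d)
  Fv <- numeric(d)
  for (f in sel) {
    el <- bg$owner[f]
    g <- matrix(grads[el, ], d, d)
    pm <- mean(state$p[bg$faces[f, ]])
    sig <- -pm * diag(d) + props$mu * (g + t(g))
    Fv <- Fv + as.numeric(sig %*% bg$normal[f, ]) * bg$measure[f]
  }
  list(force = Fv, hdf = Fv[d])
}

rbind_grad <- function(gs, d) {
  do.call(rbind, lapply(gs, function(g) matrix(g, nrow = dim(g)[1], ncol = d * d)))
}

#' Wall force from the discrete reaction residual
#'
#' Independent cross-check of [hemodynamic_force()]: the momentum residual of
#' the unconstrained discrete operator, summed over wall nodes, equals the
#' discrete wall traction in the same sign convention as the traction
#' integral (n outward from the fluid).
#'
#' @param state `lv_flow_state` carrying the solver's `reaction` field.
#' @return length-d force vector (N or N/m).
#' @export
reaction_force <- function(state) {
  if (is.null(state$reaction)) stopf("state carries no reaction residual (not produced by the solver?)")
  wn <- boundary_nodes(state$mesh, "wall")
  colSums(state$reaction[wn, , drop = FALSE])
}

#' Flow rate through the IO boundary
#'
#' \eqn{Q = \int_{IO} v\cdot n\, dA} with n outward (outflow positive);
#' in 2D the line-integral analogue Q' (m^2/s).
#'
#' @param state `lv_flow_state`.
#' @return m^3/s (3D) or m^2/s (2D).
#' @export
flow_rate <- function(state) {
  if (!any(state$mesh$btag == "io")) stopf("mesh has no io-tagged boundary")
  bg <- boundary_geometry(state$mesh)
  face_flux(state$mesh, bg, state$v, "io")
}

#' Stroke volume with flux cross-check
#'
#' SV = V_ED - V_ES; when a flow-rate series is supplied the alternative
#' estimate \eqn{\int Q\,dt} over systole and the relative discrepancy are
#' returned as well.
#'
#' @param v_ed,v_es lumen volumes at end diastole / end systole (any
#'   consistent unit).
#' @param Q,t optional flow-rate samples and times covering systole.
#' @param systole_end time at end systole (same unit as `t`).
#' @return list `sv`, and when Q is given `sv_flux`, `discrepancy`
#'   (|sv - sv_flux| / sv).
#' @export
stroke_volume <- function(v_ed, v_es, Q = NULL, t = NULL, systole_end = NULL) {
  if (v_es > v_ed) warnf("V_ES > V_ED: negative stroke volume")
  sv <- v_ed - v_es
  out <- list(sv = sv)
  if (!is.null(Q)) {
    if (is.null(t) || is.null(systole_end)) stopf("flux cross-check needs t and systole_end")
    sel <- t <= systole_end + 1e-12
    ts <- t[sel]; Qs <- Q[sel]
    ## right-Riemann sum: consistent with implicit-Euler flow-rate samples,
    ## which represent the mean flux over (t_{n-1}, t_n]
    sv_flux <- sum(diff(ts) * Qs[-1])
    out$sv_flux <- sv_flux
    out$discrepancy <- abs(sv - sv_flux) / max(abs(sv), 1e-300)
  }
  out
}

#' Kinetic-energy power through the IO boundary
#'
#' \eqn{P = \int_{IO} KE\,(v\cdot n)\,dA}: rate at which flow kinetic energy
#' leaves (positive) or enters (negative) the lumen. The cubic integrand is
#' integrated with degree-3 quadrature on each IO face (exact for the linear
#' velocity interpolation).
#'
#' @param state `lv_flow_state`.
#' @param props [fluid_props()].
#' @return W (3D) or W per metre depth (2D).
#' @export
io_power <- function(state, props = fluid_props()) {
  mesh <- state$mesh
  if (!any(mesh$btag == "io")) stopf("mesh has no io-tagged boundary")
  bg <- boundary_geometry(mesh)
  sel <- which(bg$tag == "io")
  tot <- 0
  if (mesh$dim == 2) {
    gp <- (1 + c(-1, 1) / sqrt(3)) / 2            # 2-point Gauss on [0,1]
    for (f in sel) {
      va <- state$v[bg$faces[f, 1], ]; vb <- state$v[bg$faces[f, 2], ]
      nrm <- bg$normal[f, ]
      for (q in gp) {
        vq <- (1 - q) * va + q * vb
        tot <- tot + 0.5 * bg$measure[f] *
          (0.5 * props$rho * sum(vq^2)) * sum(vq * nrm)
      }
    }
  } else {
    ## degree-3 rule on the triangle
    bc <- rbind(c(1, 1, 1) / 3, c(.6, .2, .2), c(.2, .6, .2), c(.2, .2, .6))
    wq <- c(-27, 25, 25, 25) / 48
    for (f in sel) {
      vf <- state$v[bg$faces[f, ], , drop = FALSE]
      nrm <- bg$normal[f, ]
      for (q in 1:4) {
        vq <- as.numeric(bc[q, ] %*% vf)
        tot <- tot + wq[q] * bg$measure[f] *
          (0.5 * props$rho * sum(vq^2)) * sum(vq * nrm)
      }
    }
  }
  unname(tot)
}

#' Hemodynamic time series over a simulated cycle
#'
#' Evaluates all energetics on every stored state of a [solve_cycle()]
#' result: lumen area/volume, IO flow rate (with the -dV/dt cross-check),
#' spatial KE average, vorticity magnitude and balance averages,
#' hemodynamic force and its vertical (base-apex) HDF component, and IO
#' power. Units: mm^2 and mm^2/s in 2D; mL and mL/s in 3D; KE J/m^3;
#' vorticity 1/s; force N (2D: N per metre depth); power mW.
#'
#' @param cyc an `lv_cycle` from [solve_cycle()].
#' @param props [fluid_props()] (defaults to the cycle's).
#' @return data frame of class `lv_hemo_series`, one row per stored state,
#'   with the stroke volume and flux cross-check in attributes `sv`.
#' @export
hemo_series <- function(cyc, props = NULL) {
  props <- props %||% cyc$props
  states <- cyc$states
  d <- states[[1]]$mesh$dim
  sc_meas <- 1e6                                  # m^2 -> mm^2 | m^3 -> mL
  rows <- lapply(states, function(st) {
    va <- vorticity_averages(st)
    hf <- hemodynamic_force(st, props)
    meas <- mesh_measure(st$mesh)
    data.frame(T = st$phase, t = st$t,
               measure = meas * sc_meas,
               Q = flow_rate(st) * sc_meas,
               ke_avg = ke_average(st, props),
               vort_mag_avg = va[["vort_mag_avg"]],
               vort_avg = va[["vort_avg"]],
               hdf = hf$hdf,
               f1 = hf$force[1], f2 = hf$force[2],
               f3 = if (d == 3) hf$force[3] else NA_real_,
               P = io_power(st, props) * 1e3)     # W -> mW
  })
  out <- do.call(rbind, rows)
  out$T[1] <- 0
  out$dVdt <- c(NA, diff(out$measure) / diff(out$t))
  sf <- cyc$motion$cycle$systole_fraction
  ## stroke volume over the last stored cycle
  i_ed <- 1L
  i_es <- which.min(abs(out$T - sf))
  sv <- stroke_volume(out$measure[i_ed], out$measure[i_es],
                      Q = out$Q, t = out$t,
                      systole_end = out$t[i_es])
  attr(out, "sv") <- sv
  attr(out, "space_dim") <- d
  class(out) <- c("lv_hemo_series", "data.frame")
  out
}

#' @export
print.lv_hemo_series <- function(x, ...) {
  d <- attr(x, "space_dim")
  un <- if (d == 3) c("mL", "mL/s") else c("mm^2", "mm^2/s")
  sv <- attr(x, "sv")
  cat(sprintf("<lv_hemo_series> %d samples; measure %s, Q %s\n", nrow(x), un[1], un[2]))
  cat(sprintf("  SV = %.4g (flux est. %.4g, discrepancy %.2f%%)\n",
              sv$sv, sv$sv_flux %||% NA, 100 * (sv$discrepancy %||% NA)))
  cat(sprintf("  peak |Q| = %.4g %s, peak KEavg = %.4g J/m^3, peak |P| = %.4g mW\n",
              max(abs(x$Q)), un[2], max(x$ke_avg), max(abs(x$P))))
  invisible(x)
}

#' Plot hemodynamic series over the normalized cycle
#'
#' Panels of lumen measure, flow rate, KE average, vorticity averages, HDF
#' and power against T in [0, 1]; end systole is marked by a vertical line.
#'
#' @param x `lv_hemo_series`.
#' @param es normalized end-systolic time for the marker (default 0.4).
#' @param ... unused.
#' @export
plot.lv_hemo_series <- function(x, es = 0.4, ...) {
  op <- par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  panel <- function(y, lab) {
    plot(x$T, y, type = "l", xlab = "T", ylab = lab)
    abline(v = es, col = "grey")
  }
  d <- attr(x, "space_dim")
  panel(x$measure, if (d == 3) "V [mL]" else "A [mm^2]")
  panel(x$Q, if (d == 3) "Q [mL/s]" else "Q' [mm^2/s]")
  panel(x$ke_avg, "KE avg [J/m^3]")
  panel(x$vort_mag_avg, "|Omega| avg [1/s]")
  panel(x$hdf, if (d == 3) "HDF [N]" else "HDF [N/m]")
  panel(x$P, "P [mW]")
  invisible(x)
}
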