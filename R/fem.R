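## Linear finite-element kernels shared by the flow solver, the harmonic mesh
## extension and the energetics integrals. Velocity and pressure both use
## continuous linear (P1 on triangles/tetrahedra) or bilinear (Q1 on
## quadrilaterals) nodal shape functions; pressure is stabilized (see solver).

## Gauss points for the reference square [-1,1]^2
.gp_quad <- (function() {
  g <- 1 / sqrt(3)
  list(xi = c(-g, g, g, -g), eta = c(-g, -g, g, g), w = rep(1, 4))
})()

q1_shape <- function(xi, eta) {
  N <- c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
         (1 + xi) * (1 + eta), (1 - xi) * (1 + eta)) / 4
  dN <- cbind(c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)) / 4,
              c(-(1 - xi), -(1 + xi), (1 + xi), (1 - xi)) / 4)
  list(N = N, dN = dN)
}

## Element gradient data.
## For tri/tet: constant gradients g [m x k x d], measure vector.
tri_gradients <- function(nodes, tri) {
  x <- matrix(nodes[tri, 1], ncol = 3); y <- matrix(nodes[tri, 2], ncol = 3)
  a2 <- (x[, 2] - x[, 1]) * (y[, 3] - y[, 1]) - (y[, 2] - y[, 1]) * (x[, 3] - x[, 1])
  g <- array(0, c(nrow(tri), 3, 2))
  g[, 1, 1] <- (y[, 2] - y[, 3]) / a2; g[, 1, 2] <- (x[, 3] - x[, 2]) / a2
  g[, 2, 1] <- (y[, 3] - y[, 1]) / a2; g[, 2, 2] <- (x[, 1] - x[, 3]) / a2
  g[, 3, 1] <- (y[, 1] - y[, 2]) / a2; g[, 3, 2] <- (x[, 2] - x[, 1]) / a2
  list(g = g, measure = a2 / 2)
}

tet_gradients <- function(nodes, tet) {
  m <- nrow(tet)
  p1 <- nodes[tet[, 1], , drop = FALSE]
  e1 <- nodes[tet[, 2], , drop = FALSE] - p1
  e2 <- nodes[tet[, 3], , drop = FALSE] - p1
  e3 <- nodes[tet[, 4], , drop = FALSE] - p1
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  c23 <- cr(e2, e3); c31 <- cr(e3, e1); c12 <- cr(e1, e2)
  det6 <- rowSums(e1 * c23)                       # 6V
  g <- array(0, c(m, 4, 3))
  g[, 2, ] <- c23 / det6
  g[, 3, ] <- c31 / det6
  g[, 4, ] <- c12 / det6
  g[, 1, ] <- -(g[, 2, ] + g[, 3, ] + g[, 4, ])
  list(g = g, measure = det6 / 6)
}

## Triplet accumulator for sparse assembly
trip_new <- function() new.env(parent = emptyenv())
trip_add <- function(tr, name, i, j, x) {
  tr[[name]] <- c(tr[[name]], list(list(i = i, j = j, x = x)))
}
trip_mat <- function(tr, name, n, ncol_ = n) {
  parts <- tr[[name]]
  if (is.null(parts)) return(Matrix::sparseMatrix(i = integer(), j = integer(),
                                                  x = numeric(), dims = c(n, ncol_)))
  i <- unlist(lapply(parts, `[[`, "i")); j <- unlist(lapply(parts, `[[`, "j"))
  x <- unlist(lapply(parts, `[[`, "x"))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, ncol_))
}

## Simplex (tri/tet) block assembly, fully vectorized across elements.
## Adds triplets for K (stiffness), M (mass), D[k] (int phi_i d(phi_j)/dx_k),
## S (delta-weighted stiffness) and C (convection (a.grad u, phi)).
assemble_simplex <- function(tr, elem, gd, a, delta, dim) {
  m <- nrow(elem); k <- ncol(elem)
  g <- gd$g; meas <- gd$measure
  mfac <- if (k == 3) 12 else 20                  # consistent P1 mass factor
  for (i in seq_len(k)) for (j in seq_len(k)) {
    gg <- rowSums(g[, i, , drop = FALSE] * g[, j, , drop = FALSE])
    trip_add(tr, "K", elem[, i], elem[, j], meas * gg)
    if (!is.null(delta)) trip_add(tr, "S", elem[, i], elem[, j], delta * meas * gg)
    trip_add(tr, "M", elem[, i], elem[, j], meas / mfac * (1 + (i == j)))
    for (d in seq_len(dim))
      trip_add(tr, paste0("D", d), elem[, i], elem[, j], meas / k * g[, j, d])
  }
  if (!is.null(a)) {
    ## adot[,l,j] = a(node l) . grad(phi_j)
    adot <- array(0, c(m, k, k))
    for (l in seq_len(k)) for (j in seq_len(k)) {
      s <- 0
      for (d in seq_len(dim)) s <- s + a[elem[, l], d] * g[, j, d]
      adot[, l, j] <- s
    }
    sum_l <- apply(adot, c(1, 3), sum)
    for (i in seq_len(k)) for (j in seq_len(k))
      trip_add(tr, "C", elem[, i], elem[, j], meas / mfac * (sum_l[, j] + adot[, i, j]))
  }
  invisible(NULL)
}

## Q1 quadrilateral assembly with 2x2 Gauss quadrature, vectorized per point.
assemble_quad <- function(tr, quad, nodes, a, delta) {
  m <- nrow(quad)
  xs <- matrix(nodes[quad, 1], ncol = 4); ys <- matrix(nodes[quad, 2], ncol = 4)
  for (q in seq_along(.gp_quad$w)) {
    sh <- q1_shape(.gp_quad$xi[q], .gp_quad$eta[q])
    N <- sh$N; dN <- sh$dN
    j11 <- xs %*% dN[, 1]; j21 <- ys %*% dN[, 1]     # d/dxi
    j12 <- xs %*% dN[, 2]; j22 <- ys %*% dN[, 2]     # d/deta
    detJ <- as.numeric(j11 * j22 - j12 * j21)
    w <- .gp_quad$w[q] * detJ
    ## grad phi_i = invJ^T %*% dN_i
    gx <- matrix(0, m, 4); gy <- matrix(0, m, 4)
    for (i in 1:4) {
      gx[, i] <- ( j22 * dN[i, 1] - j21 * dN[i, 2]) / detJ
      gy[, i] <- (-j12 * dN[i, 1] + j11 * dN[i, 2]) / detJ
    }
    if (!is.null(a)) {
      agx <- matrix(a[quad, 1], ncol = 4) %*% N     # a_x at gp
      agy <- matrix(a[quad, 2], ncol = 4) %*% N
    }
    for (i in 1:4) for (j in 1:4) {
      kk <- w * (gx[, i] * gx[, j] + gy[, i] * gy[, j])
      trip_add(tr, "K", quad[, i], quad[, j], kk)
      if (!is.null(delta)) trip_add(tr, "S", quad[, i], quad[, j], delta * kk)
      trip_add(tr, "M", quad[, i], quad[, j], w * N[i] * N[j])
      trip_add(tr, "D1", quad[, i], quad[, j], w * N[i] * gx[, j])
      trip_add(tr, "D2", quad[, i], quad[, j], w * N[i] * gy[, j])
      if (!is.null(a))
        trip_add(tr, "C", quad[, i], quad[, j],
                 w * N[i] * (as.numeric(agx) * gx[, j] + as.numeric(agy) * gy[, j]))
    }
  }
  invisible(NULL)
}

## Element sizes h_K (sqrt area / cbrt volume) in canonical order tri,quad,tet
element_sizes <- function(mesh) {
  h <- numeric(0)
  if (nrow(mesh$tri)) h <- c(h, sqrt(2 * abs(tri_areas(mesh$nodes, mesh$tri))))
  if (nrow(mesh$quad)) {
    cj <- quad_corner_jacobians(mesh$nodes, mesh$quad)
    h <- c(h, sqrt(abs(rowSums(cj) / 4)))
  }
  if (nrow(mesh$tet)) h <- c(h, (6 * abs(tet_volumes(mesh$nodes, mesh$tet)))^(1 / 3))
  h
}

## Element mean convection speed |a| in canonical order
element_speed <- function(mesh, a) {
  sp <- sqrt(rowSums(a^2))
  out <- numeric(0)
  if (nrow(mesh$tri)) out <- c(out, rowMeans(matrix(sp[mesh$tri], ncol = 3)))
  if (nrow(mesh$quad)) out <- c(out, rowMeans(matrix(sp[mesh$quad], ncol = 4)))
  if (nrow(mesh$tet)) out <- c(out, rowMeans(matrix(sp[mesh$tet], ncol = 4)))
  out
}

## Assemble scalar FEM operators on a mesh.
##   a:     n x d nodal convection velocity (or NULL to skip C)
##   delta: per-element pressure-stabilization weight (or NULL to skip S)
## Returns sparse n x n matrices K, M, D[[k]], and C, S when requested.
assemble_fem <- function(mesh, a = NULL, delta = NULL) {
  n <- nrow(mesh$nodes)
  tr <- trip_new()
  ofs <- 0
  take <- function(m) { idx <- ofs + seq_len(m); ofs <<- ofs + m; idx }
  if (nrow(mesh$tri)) {
    d <- if (!is.null(delta)) delta[take(nrow(mesh$tri))]
    assemble_simplex(tr, mesh$tri, tri_gradients(mesh$nodes, mesh$tri), a, d, 2)
  }
  if (nrow(mesh$quad)) {
    d <- if (!is.null(delta)) delta[take(nrow(mesh$quad))]
    assemble_quad(tr, mesh$quad, mesh$nodes, a, d)
  }
  if (nrow(mesh$tet)) {
    d <- if (!is.null(delta)) delta[take(nrow(mesh$tet))]
    assemble_simplex(tr, mesh$tet, tet_gradients(mesh$nodes, mesh$tet), a, d, 3)
  }
  out <- list(K = trip_mat(tr, "K", n), M = trip_mat(tr, "M", n))
  for (k in seq_len(mesh$dim)) out[[paste0("D", k)]] <- trip_mat(tr, paste0("D", k), n)
  if (!is.null(a)) out$C <- trip_mat(tr, "C", n)
  if (!is.null(delta)) out$S <- trip_mat(tr, "S", n)
  out
}

## ---- boundary face geometry ----------------------------------------------

## Outward unit normals and measures for boundary faces. Orientation is fixed
## geometrically: the normal points away from the centroid of the owning
## element.
boundary_geometry <- function(mesh) {
  bf <- mesh$bfaces
  if (is.null(bf) || !nrow(bf)) stopf("mesh has no tagged boundary")
  n <- nrow(bf)
  nodes <- mesh$nodes
  ## owning element centroid per face: match faces to elements by node sets
  all_el <- rbind(
    if (nrow(mesh$tri)) cbind(mesh$tri, NA),
    if (nrow(mesh$quad)) mesh$quad,
    if (nrow(mesh$tet)) mesh$tet)
  owner <- mesh$bowner
  if (is.null(owner)) {
    nn <- nrow(nodes)
    ## node -> elements incidence
    ev <- as.vector(all_el); ee <- rep(seq_len(nrow(all_el)), times = ncol(all_el))
    keep <- !is.na(ev)
    el_of_node <- split(ee[keep], ev[keep])
    el_of_node <- el_of_node[as.character(seq_len(nn))]
    owner <- integer(n)
    for (f in seq_len(n)) {
      cand <- el_of_node[[bf[f, 1]]]
      for (v in bf[f, -1]) cand <- intersect(cand, el_of_node[[v]])
      owner[f] <- cand[1]
    }
  }
  ecent <- t(vapply(owner, function(e) {
    vs <- all_el[e, ]; vs <- vs[!is.na(vs)]
    colMeans(nodes[vs, , drop = FALSE])
  }, numeric(mesh$dim)))
  if (mesh$dim == 2) {
    t1 <- nodes[bf[, 2], ] - nodes[bf[, 1], ]
    len <- sqrt(rowSums(t1^2))
    nor <- cbind(t1[, 2], -t1[, 1]) / len
    meas <- len
    fcent <- (nodes[bf[, 1], ] + nodes[bf[, 2], ]) / 2
  } else {
    e1 <- nodes[bf[, 2], ] - nodes[bf[, 1], ]
    e2 <- nodes[bf[, 3], ] - nodes[bf[, 1], ]
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    a2 <- sqrt(rowSums(cr^2))
    nor <- cr / a2
    meas <- a2 / 2
    fcent <- (nodes[bf[, 1], ] + nodes[bf[, 2], ] + nodes[bf[, 3], ]) / 3
  }
  flip <- rowSums(nor * (fcent - ecent)) < 0
  nor[flip, ] <- -nor[flip, , drop = FALSE]
  list(faces = bf, tag = mesh$btag, normal = nor, measure = meas,
       owner = owner, center = fcent)
}

## Integral of (v . n) over boundary faces with a given tag (linear v, exact).
face_flux <- function(mesh, bg, v, tag) {
  sel <- which(bg$tag %in% tag)
  if (!length(sel)) return(0)
  tot <- 0
  k <- ncol(bg$faces)
  for (f in sel) {
    vm <- colMeans(v[bg$faces[f, ], , drop = FALSE])
    tot <- tot + sum(vm * bg$normal[f, ]) * bg$measure[f]
  }
  unname(tot)
}

## Boundary mass-type matrix weighted by nodal coefficient beta (>=0), used
## for backflow stabilization on the IO boundary: int beta phi_i phi_j.
boundary_weighted_mass <- function(mesh, bg, beta, tag) {
  sel <- which(bg$tag %in% tag)
  nn <- nrow(mesh$nodes)
  if (!length(sel)) return(Matrix::sparseMatrix(i = integer(), j = integer(),
                                                x = numeric(), dims = c(nn, nn)))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  k <- ncol(bg$faces)
  mloc <- if (k == 2) matrix(c(2, 1, 1, 2) / 6, 2) else
    matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2) / 12, 3)
  for (f in sel) {
    vs <- bg$faces[f, ]
    bmean <- mean(beta[vs])
    if (bmean <= 0) next
    loc <- bmean * bg$measure[f] * mloc
    ii <- c(ii, rep(vs, each = k)); jj <- c(jj, rep(vs, times = k))
    xx <- c(xx, as.numeric(t(loc)))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nn, nn))
}
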