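## Semi-automatic LV lumen delineation: Perona-Malik diffusion pre-filter,
## fuzzy c-means intensity clustering, lumen-region selection near a user
## hint, sub-pixel boundary tracing with circularity/location filtering,
## active-contour (snake) refinement, and neighbour-averaging smoothing.

#' Edge-preserving anisotropic diffusion (Perona-Malik)
#'
#' Explicit 4-neighbour scheme with the exponential conductance
#' \eqn{g(s) = \exp(-(s/\kappa)^2)}. The update is a convex combination of
#' neighbour values, so intensity extrema are never amplified.
#'
#' @param image 2D numeric matrix.
#' @param iterations number of diffusion sweeps (default 10).
#' @param kappa conductance scale; default 10 percent of the intensity range.
#' @param lambda step size, must satisfy lambda <= 0.25 for stability.
#' @return smoothed image, same shape.
#' @export
anisotropic_diffusion <- function(image, iterations = 10, kappa = NULL,
                                  lambda = 0.2) {
  if (!is.matrix(image)) stopf("image must be a 2D matrix")
  if (iterations <= 0) stopf("iterations must be positive")
  if (lambda <= 0 || lambda > 0.25) stopf("lambda must be in (0, 0.25]")
  rng <- diff(range(image))
  if (rng == 0) return(image)
  kappa <- kappa %||% (0.1 * rng)
  u <- image
  nr <- nrow(u); nc <- ncol(u)
  g <- function(s) exp(-(s / kappa)^2)
  for (it in seq_len(iterations)) {
    dN <- rbind(u[1, , drop = FALSE], u[-nr, , drop = FALSE]) - u
    dS <- rbind(u[-1, , drop = FALSE], u[nr, , drop = FALSE]) - u
    dW <- cbind(u[, 1, drop = FALSE], u[, -nc, drop = FALSE]) - u
    dE <- cbind(u[, -1, drop = FALSE], u[, nc, drop = FALSE]) - u
    u <- u + lambda * (g(dN) * dN + g(dS) * dS + g(dW) * dW + g(dE) * dE)
  }
  u
}

#' Fuzzy c-means clustering of image intensities
#'
#' Minimizes \eqn{J = \sum_i \sum_j u_{ij}^m \lVert q_i - c_j \rVert^2} by
#' alternating the reciprocal-distance membership update
#' \eqn{u_{ij} = 1 / \sum_k (\lVert q_i-c_j\rVert / \lVert q_i-c_k\rVert)^{2/(m-1)}}
#' and the weighted centroid update
#' \eqn{c_j = \sum_i u_{ij}^m q_i / \sum_i u_{ij}^m}. Cluster centres are
#' initialized by sampling the intensity range at uniform intervals and kept
#' sorted ascending, making the fit fully deterministic. By default the
#' update runs over the intensity histogram (each distinct value weighted by
#' its count), which is exactly equivalent to the per-pixel update.
#'
#' @param image numeric matrix (or vector) of intensities.
#' @param C number of clusters (>= 2); 10 is the working default for
#'   short-axis frames.
#' @param m fuzzy exponent, > 1 (default 2).
#' @param tol convergence threshold on |dJ| (default 1e-6, relative to J).
#' @param max_iter iteration cap.
#' @param use_histogram cluster over distinct intensities with counts
#'   (exact; fast for quantized images) instead of per-pixel.
#' @return object of class `lv_fcm`: `centers` (ascending), `J` (objective
#'   trace, non-increasing), `memberships` (pixels x C), `hard` (max-
#'   membership labels, ties to the lowest cluster index), `degenerate`
#'   (TRUE when all intensities coincide).
#' @export
fcm_segment <- function(image, C = 10, m = 2, tol = 1e-6, max_iter = 200,
                        use_histogram = TRUE) {
  if (C < 2) stopf("C must be >= 2")
  if (m <= 1) stopf("fuzzy exponent m must be > 1")
  x <- as.numeric(image)
  rng <- range(x)
  if (diff(rng) == 0) {
    u <- matrix(1 / C, length(x), C)
    return(structure(list(centers = rep(x[1], C), J = 0, memberships = u,
                          hard = rep(1L, length(x)), degenerate = TRUE,
                          C = C, m = m, dim = dim(image)),
                     class = "lv_fcm"))
  }
  if (use_histogram) {
    tb <- table(x)
    q <- as.numeric(names(tb)); w <- as.numeric(tb)
  } else {
    q <- x; w <- rep(1, length(x))
  }
  ## centres: uniform intervals of the intensity range (midpoints)
  centers <- rng[1] + (seq_len(C) - 0.5) / C * diff(rng)
  memb_of <- function(q, centers) {
    dmat <- abs(outer(q, centers, "-"))
    zero <- dmat < .Machine$double.eps
    pw <- dmat^(-2 / (m - 1))
    u <- pw / rowSums(pw)
    zr <- rowSums(zero) > 0
    if (any(zr)) u[zr, ] <- zero[zr, , drop = FALSE] / rowSums(zero[zr, , drop = FALSE])
    u
  }
  Jtrace <- numeric(0)
  for (it in seq_len(max_iter)) {
    u <- memb_of(q, centers)
    um <- u^m
    J <- sum(w * rowSums(um * abs(outer(q, centers, "-"))^2))
    Jtrace <- c(Jtrace, J)
    centers_new <- colSums(w * um * q) / colSums(w * um)
    centers_new <- sort(centers_new)
    if (it > 1 && abs(Jtrace[it - 1] - J) < tol * max(Jtrace[1], 1)) {
      centers <- centers_new
      break
    }
    centers <- centers_new
  }
  u_pix <- memb_of(x, centers)
  hard <- max.col(u_pix, ties.method = "first")
  structure(list(centers = centers, J = Jtrace, memberships = u_pix,
                 hard = as.integer(hard), degenerate = FALSE,
                 C = C, m = m, dim = dim(image)),
            class = "lv_fcm")
}

#' @export
print.lv_fcm <- function(x, ...) {
  cat(sprintf("<lv_fcm> C = %d, m = %g, %d iterations, J = %.6g\n",
              x$C, x$m, length(x$J), tail(x$J, 1)))
  cat("  centers:", paste(sprintf("%.2f", x$centers), collapse = " "), "\n")
  invisible(x)
}

#' Cluster-count diagnostic
#'
#' Reports, for a range of cluster counts, the mean inter-cluster centre
#' distance and the circularity of the candidate lumen region, supporting a
#' manual choice of C (the criterion is reported, not optimized
#' automatically).
#'
#' @param image intensity matrix.
#' @param center_hint (row, col) approximate lumen centre.
#' @param C_range candidate cluster counts.
#' @param ... passed to [fcm_segment()].
#' @return data frame with columns C, mean_center_distance,
#'   lumen_circularity.
#' @export
fcm_cluster_diagnostic <- function(image, center_hint, C_range = 4:12, ...) {
  rows <- lapply(C_range, function(C) {
    fit <- fcm_segment(image, C = C, ...)
    circ <- tryCatch({
      mask <- select_lumen_region(fit, image, center_hint)
      tr <- extract_and_filter_traces(mask, min_circularity = 0)
      tr$circularity
    }, error = function(e) NA_real_)
    data.frame(C = C,
               mean_center_distance = mean(diff(fit$centers)),
               lumen_circularity = circ)
  })
  do.call(rbind, rows)
}

#' Select the lumen region from a fuzzy c-means fit
#'
#' The clusters closest to the ventricle centre are identified as those
#' whose maximum-membership assignments dominate a small window around the
#' user hint (with noisy data the lumen intensity mode spreads over a few
#' adjacent clusters). Their combined membership is thresholded at 0.5,
#' giving the candidate lumen pixels; among the connected regions whose
#' centroid-to-hint distance falls in the closest decile, the largest-area
#' region is returned after minimal morphological closing (and filling of
#' enclosed speckle holes -- the lumen is simply connected).
#'
#' @param model `lv_fcm` fit of `image`.
#' @param image the clustered intensity matrix (defines the shape).
#' @param center_hint (row, col) approximate ventricle centre, 0-based.
#' @param search_radius maximal acceptable hint-to-centroid distance in
#'   pixels (default a quarter of the smaller image dimension); beyond it a
#'   "lumen not found" error is raised (the manual-retrace path).
#' @param hint_window half-width of the window defining the centre clusters.
#' @param brush diameter of the closing structuring element (odd, default 5).
#' @return logical lumen mask.
#' @export
select_lumen_region <- function(model, image, center_hint,
                                search_radius = NULL, hint_window = 3,
                                brush = 5) {
  nr <- nrow(image); nc <- ncol(image)
  if (center_hint[1] < 0 || center_hint[1] > nr - 1 ||
      center_hint[2] < 0 || center_hint[2] > nc - 1)
    stopf("center_hint is outside the image")
  search_radius <- search_radius %||% (0.25 * min(nr, nc))
  labels <- matrix(model$hard, nr, nc)
  hr <- round(center_hint[1]) + 1L; hc <- round(center_hint[2]) + 1L
  win <- labels[max(1, hr - hint_window):min(nr, hr + hint_window),
                max(1, hc - hint_window):min(nc, hc + hint_window)]
  tb <- table(win)
  lead <- as.integer(names(tb)[which.max(tb)])
  ## the intensity mode at the hint usually spreads over several adjacent
  ## clusters: merge centres separated by small gaps into one mode and take
  ## the mode containing the window-majority cluster
  cen <- model$centers
  gaps <- diff(cen)
  brk <- which(gaps > 0.1 * max(diff(range(cen)), .Machine$double.eps))
  grp <- cumsum(c(1L, as.integer(seq_along(gaps) %in% brk)))
  center_clusters <- which(grp == grp[lead])
  memb <- rowSums(model$memberships[, center_clusters, drop = FALSE])
  mask0 <- matrix(memb > 0.5, nr, nc)
  lab <- EBImage::bwlabel(mask0)
  n_comp <- max(lab)
  if (n_comp == 0) stopf("lumen not found: no region near the hint")
  idx <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[lab > 0]
  ar <- tabulate(comp, n_comp)
  cr <- as.numeric(tapply(idx[, 1] - 1, comp, mean))
  cc <- as.numeric(tapply(idx[, 2] - 1, comp, mean))
  dists <- sqrt((cr - center_hint[1])^2 + (cc - center_hint[2])^2)
  if (min(dists) > search_radius)
    stopf("lumen not found within %.0f px of the hint (manual retrace needed)",
          search_radius)
  cut <- stats::quantile(dists, 0.1)
  cand <- which(dists <= max(cut, min(dists)))
  best <- cand[which.max(ar[cand])]
  mask <- lab == best
  kern <- EBImage::makeBrush(brush, shape = "disc")
  mask <- EBImage::closing(mask, kern) > 0
  mask <- EBImage::fillHull(mask) > 0
  mask
}

## rasterize a closed (row, col) polygon into a logical mask (pixel centres)
fill_trace_mask <- function(trace, nr, nc) {
  pts <- trace$points
  n <- nrow(pts)
  mask <- matrix(FALSE, nr, nc)
  ry <- pts[, 1]; cx <- pts[, 2]
  jn <- c(2:n, 1)
  for (r in seq_len(nr)) {
    y <- r - 1
    i <- which((ry <= y & ry[jn] > y) | (ry[jn] <= y & ry > y))
    if (!length(i)) next
    xs <- cx[i] + (y - ry[i]) / (ry[jn][i] - ry[i]) * (cx[jn][i] - cx[i])
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      c0 <- max(1, ceiling(xs[k] + 1)); c1 <- min(nc, floor(xs[k + 1] + 1))
      if (c0 <= c1) mask[r, c0:c1] <- TRUE
    }
  }
  mask
}

#' Trace and filter the lumen boundary of a mask
#'
#' Extracts the boundary of the largest connected component as a closed
#' sub-pixel polyline (marching-squares isoline at level 0.5), orients it
#' counter-clockwise in (col, row) pixel coordinates, and filters it:
#' traces whose circularity \eqn{4\pi A/P^2} falls below `min_circularity`,
#' or whose centroid leaves the expected window, are returned as an
#' `lv_trace_rejected` carrying the reason.
#'
#' @param mask logical/0-1 matrix.
#' @param min_circularity rejection threshold (default 0.5).
#' @param centroid_window optional `c(row_min, row_max, col_min, col_max)`
#'   expected centroid box (default: the central third of the image).
#' @param smooth_window odd moving-average window applied along the contour
#'   to suppress pixel-level jaggedness before the circularity test
#'   (default 5; 1 = off).
#' @return `lv_trace` with `points` (n x 2, 0-based continuous (row, col)),
#'   `circularity`, `area`, `centroid`; or `lv_trace_rejected`.
#' @export
extract_and_filter_traces <- function(mask, min_circularity = 0.5,
                                      centroid_window = NULL,
                                      smooth_window = 5) {
  mask <- mask > 0
  if (!any(mask)) stopf("empty mask: nothing to trace")
  lab <- EBImage::bwlabel(mask)
  ar <- tabulate(lab[lab > 0])
  big <- which.max(ar)
  comp <- lab == big
  nr <- nrow(comp); nc <- ncol(comp)
  ## pad so boundary components touching the edge still close
  z <- matrix(0, nr + 2, nc + 2)
  z[2:(nr + 1), 2:(nc + 1)] <- comp
  cl <- contourLines(x = seq_len(nr + 2) - 2, y = seq_len(nc + 2) - 2,
                     z = z, levels = 0.5)
  if (!length(cl)) stopf("no contour found in mask")
  len <- vapply(cl, function(c0) length(c0$x), 1L)
  c0 <- cl[[which.max(len)]]
  pts <- cbind(row = c0$x, col = c0$y)
  if (nrow(pts) > 1 &&
      isTRUE(all.equal(pts[1, ], pts[nrow(pts), ], check.attributes = FALSE)))
    pts <- pts[-nrow(pts), , drop = FALSE]
  if (smooth_window > 1 && nrow(pts) > 2 * smooth_window) {
    pts <- cbind(circular_moving_average(pts[, 1], smooth_window),
                 circular_moving_average(pts[, 2], smooth_window))
    colnames(pts) <- c("row", "col")
  }
  ## CCW in (col, row) axes
  if (polygon_area(pts[, c(2, 1)]) < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
  area <- abs(polygon_area(pts[, c(2, 1)]))
  circ <- circularity(pts[, c(2, 1)])
  cen <- polygon_centroid(pts)                    # (row, col)
  tr <- structure(list(points = pts, circularity = circ, area = area,
                       centroid = cen),
                  class = "lv_trace")
  if (circ < min_circularity)
    return(structure(list(trace = tr,
                          reason = sprintf("circularity %.3f below threshold %.3f",
                                           circ, min_circularity)),
                     class = "lv_trace_rejected"))
  cw <- centroid_window %||% c(nr / 3, 2 * nr / 3, nc / 3, 2 * nc / 3)
  if (cen[1] < cw[1] || cen[1] > cw[2] || cen[2] < cw[3] || cen[2] > cw[4])
    return(structure(list(trace = tr,
                          reason = sprintf("centroid (%.1f, %.1f) outside expected window",
                                           cen[1], cen[2])),
                     class = "lv_trace_rejected"))
  tr
}

#' @export
print.lv_trace <- function(x, ...) {
  cat(sprintf("<lv_trace> %d points, area %.1f px^2, circularity %.3f\n",
              nrow(x$points), x$area, x$circularity))
  invisible(x)
}

#' @export
print.lv_trace_rejected <- function(x, ...) {
  cat(sprintf("<lv_trace_rejected> %s\n", x$reason))
  invisible(x)
}

## bilinear interpolation of a matrix at 0-based (row, col) points
.interp2 <- function(img, rc) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(rc[, 1], 0), nr - 1); c2 <- pmin(pmax(rc[, 2], 0), nc - 1)
  r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c2), nc - 2)
  fr <- r - r0; fc <- c2 - c0
  i00 <- cbind(r0 + 1, c0 + 1); i10 <- cbind(r0 + 2, c0 + 1)
  i01 <- cbind(r0 + 1, c0 + 2); i11 <- cbind(r0 + 2, c0 + 2)
  img[i00] * (1 - fr) * (1 - fc) + img[i10] * fr * (1 - fc) +
    img[i01] * (1 - fr) * fc + img[i11] * fr * fc
}

#' Active-contour (snake) refinement of a lumen trace
#'
#' Deforms the closed polyline to minimize internal tension/stiffness energy
#' plus an external energy attracting it to strong intensity gradients
#' (negative squared gradient magnitude of the image). Implicit Euler on the
#' internal terms (pentadiagonal cyclic system), explicit on the image
#' force, the classic Kass-style scheme. If the contour collapses below 8
#' points-worth of area or self-intersects, the input trace is returned with
#' a warning.
#'
#' @param trace `lv_trace` initialized near the edge.
#' @param image intensity matrix (commonly the diffusion-filtered image).
#' @param alpha tension (first-derivative) weight.
#' @param beta stiffness (second-derivative) weight.
#' @param gamma step size.
#' @param iterations iteration count.
#' @param edge_weight scaling of the image force.
#' @param n_points contour point count; default adapts to the contour
#'   length (about 1.5 px spacing, 24 to 128 points) so the internal-energy
#'   finite differences stay well scaled for small contours.
#' @return refined `lv_trace`.
#' @export
snake_refine <- function(trace, image, alpha = 0.1, beta = 0.1, gamma = 1,
                         iterations = 100, edge_weight = 2, n_points = NULL) {
  n_points <- n_points %||%
    min(128L, max(24L, round(polygon_perimeter(trace$points) / 1.5)))
  pts <- resample_polyline(trace$points, n_points, closed = TRUE)
  n <- n_points
  ## edge map: squared gradient magnitude of the image
  gr <- (rbind(image[-1, ], image[nrow(image), ]) -
         rbind(image[1, ], image[-nrow(image), ])) / 2
  gc <- (cbind(image[, -1], image[, ncol(image)]) -
         cbind(image[, 1], image[, -ncol(image)])) / 2
  E <- gr^2 + gc^2
  E <- E / max(E, .Machine$double.eps)
  Er <- (rbind(E[-1, ], E[nrow(E), ]) - rbind(E[1, ], E[-nrow(E), ])) / 2
  Ec <- (cbind(E[, -1], E[, ncol(E)]) - cbind(E[, 1], E[, -ncol(E)])) / 2
  ## cyclic internal-energy matrix
  a2 <- alpha; b2 <- beta
  main <- 2 * a2 + 6 * b2
  off1 <- -a2 - 4 * b2
  off2 <- b2
  idx <- function(k) ((seq_len(n) - 1 + k) %% n) + 1
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), seq_len(n))] <- main
  A[cbind(seq_len(n), idx(1))] <- off1
  A[cbind(seq_len(n), idx(-1))] <- off1
  A[cbind(seq_len(n), idx(2))] <- off2
  A[cbind(seq_len(n), idx(-2))] <- off2
  Ainv <- solve(diag(n) + gamma * A)
  for (it in seq_len(iterations)) {
    fr <- edge_weight * .interp2(Er, pts)
    fc <- edge_weight * .interp2(Ec, pts)
    pts <- Ainv %*% (pts + gamma * cbind(fr, fc))
  }
  pts <- as.matrix(pts)
  ok <- abs(polygon_area(pts[, c(2, 1)])) > 2 && polygon_is_simple(pts)
  if (!ok) {
    warnf("snake collapsed or self-intersected; keeping the input trace")
    return(trace)
  }
  if (polygon_area(pts[, c(2, 1)]) < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
  structure(list(points = pts,
                 circularity = circularity(pts[, c(2, 1)]),
                 area = abs(polygon_area(pts[, c(2, 1)])),
                 centroid = polygon_centroid(pts)),
            class = "lv_trace")
}

#' Spatial smoothing of corresponding traces
#'
#' Moving average along each contour (window `window_along`) and across
#' adjacent traces at corresponding point indices (window `window_across`),
#' the final smoothing pass that removes surface irregularities before
#' reconstruction. Traces must already be resampled to a common point count.
#'
#' @param traces list of `lv_trace` (adjacent slices or phases, in order).
#' @param window_along odd window along the contour (default 5; 1 = off).
#' @param window_across odd window across traces (default 3; 1 = off).
#' @return list of smoothed `lv_trace`.
#' @export
smooth_traces <- function(traces, window_along = 5, window_across = 3) {
  np <- vapply(traces, function(t) nrow(t$points), 1L)
  if (length(unique(np)) != 1)
    stopf("traces must share a common point count (got %s)",
          paste(unique(np), collapse = ", "))
  n <- np[1]; K <- length(traces)
  arr <- array(unlist(lapply(traces, `[[`, "points")), dim = c(n, 2, K))
  if (window_along > 1) {
    for (k in seq_len(K)) for (d in 1:2)
      arr[, d, k] <- circular_moving_average(arr[, d, k], window_along)
  }
  if (window_across > 1) {
    if (K < 2) warnf("single trace: across-slice averaging skipped")
    else {
      h <- (window_across - 1) / 2
      sm <- arr
      for (k in seq_len(K)) {
        lo <- max(1, k - h); hi <- min(K, k + h)
        sm[, , k] <- apply(arr[, , lo:hi, drop = FALSE], c(1, 2), mean)
      }
      arr <- sm
    }
  }
  lapply(seq_len(K), function(k) {
    pts <- arr[, , k]
    structure(list(points = pts,
                   circularity = circularity(pts[, c(2, 1)]),
                   area = abs(polygon_area(pts[, c(2, 1)])),
                   centroid = polygon_centroid(pts)),
              class = "lv_trace")
  })
}

#' Import manual traces from CSV sidecar files
#'
#' One file per image plane, two numeric columns (row, col) per vertex of
#' the closed outline, 0-based pixel indices -- the plain-text stand-in for
#' interactive manual tracing of long-axis views.
#'
#' @param paths CSV files.
#' @return list of `lv_trace`.
#' @export
read_traces_csv <- function(paths) {
  lapply(paths, function(p) {
    d <- read.csv(p)
    if (ncol(d) < 2) stopf("%s: need two columns (row, col)", p)
    pts <- as.matrix(d[, 1:2])
    colnames(pts) <- c("row", "col")
    if (polygon_area(pts[, c(2, 1)]) < 0) pts <- pts[nrow(pts):1, ]
    structure(list(points = pts, circularity = circularity(pts[, c(2, 1)]),
                   area = abs(polygon_area(pts[, c(2, 1)])),
                   centroid = polygon_centroid(pts)),
              class = "lv_trace")
  })
}

#' Segment every frame of a cine stack
#'
#' Runs the full per-frame chain: anisotropic diffusion, fuzzy c-means
#' (C clusters), lumen-region selection near the hint, sub-pixel tracing
#' with circularity/location filtering, and optional snake refinement.
#'
#' @param stack `lv_image_stack` (or a phantom's `images` list).
#' @param center_hint (row, col) ventricle centre hint; default the image
#'   centre.
#' @param C,m fuzzy c-means settings (defaults 10 clusters, exponent 2).
#' @param diffusion_iterations pre-filter sweeps (default 10).
#' @param snake logical: refine traces with the active contour (on the
#'   diffused image).
#' @param min_circularity trace filter threshold.
#' @param quantize round diffused intensities to this step before
#'   clustering (keeps the histogram-weighted update fast; default 1.0).
#' @return list of class `lv_segmentation`: `masks[[slice]][[phase]]`,
#'   `traces[[slice]][[phase]]` (`lv_trace` or `lv_trace_rejected`), and
#'   `failures` (frames whose lumen was not found).
#' @export
segment_cine_stack <- function(stack, center_hint = NULL, C = 10, m = 2,
                               diffusion_iterations = 10, snake = TRUE,
                               min_circularity = 0.5, quantize = 1) {
  frames <- if (inherits(stack, "lv_image_stack")) stack$frames else stack
  ns <- length(frames); np <- length(frames[[1]])
  masks <- vector("list", ns); traces <- vector("list", ns)
  failures <- list()
  for (s in seq_len(ns)) {
    masks[[s]] <- vector("list", np); traces[[s]] <- vector("list", np)
    for (ph in seq_len(np)) {
      img <- frames[[s]][[ph]]
      hint <- center_hint %||% c((nrow(img) - 1) / 2, (ncol(img) - 1) / 2)
      sm <- anisotropic_diffusion(img, iterations = diffusion_iterations)
      smq <- if (quantize > 0) round(sm / quantize) * quantize else sm
      fit <- fcm_segment(smq, C = C, m = m)
      res <- tryCatch({
        mask <- select_lumen_region(fit, smq, hint)
        tr <- extract_and_filter_traces(mask, min_circularity = min_circularity)
        if (inherits(tr, "lv_trace") && snake) {
          tr <- snake_refine(tr, sm)
          ## the delineation, not the raw cluster mask, is the segmentation
          mask <- fill_trace_mask(tr, nrow(img), ncol(img))
        }
        list(mask = mask, trace = tr)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <- list(slice = s, phase = ph,
                                                 message = conditionMessage(res))
        masks[[s]][[ph]] <- matrix(FALSE, nrow(img), ncol(img))
        traces[[s]][[ph]] <- structure(list(trace = NULL,
                                            reason = conditionMessage(res)),
                                       class = "lv_trace_rejected")
      } else {
        masks[[s]][[ph]] <- res$mask
        traces[[s]][[ph]] <- res$trace
      }
    }
  }
  structure(list(masks = masks, traces = traces, failures = failures,
                 C = C, m = m),
            class = "lv_segmentation")
}

#' @export
print.lv_segmentation <- function(x, ...) {
  nf <- sum(vapply(x$traces, function(sl)
    sum(vapply(sl, inherits, TRUE, what = "lv_trace")), 1L))
  tot <- sum(vapply(x$traces, length, 1L))
  cat(sprintf("<lv_segmentation> %d/%d frames traced (%d failures)\n",
              nf, tot, length(x$failures)))
  invisible(x)
}

#' Dice overlap of a segmentation against ground-truth masks
#'
#' @param seg `lv_segmentation`.
#' @param masks ground-truth masks, `masks[[slice]][[phase]]`.
#' @return matrix n_slices x n_phases of Dice coefficients.
#' @export
segmentation_dice <- function(seg, masks) {
  ns <- length(masks); np <- length(masks[[1]])
  out <- matrix(NA_real_, ns, np)
  for (s in seq_len(ns)) for (ph in seq_len(np))
    out[s, ph] <- dice_coefficient(seg$masks[[s]][[ph]], masks[[s]][[ph]])
  out
}
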