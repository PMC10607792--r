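disk_mask <- function(n, r, cen = c((n - 1) / 2, (n - 1) / 2)) {
  rr <- matrix(rep(0:(n - 1), n), n, n)
  cc <- matrix(rep(0:(n - 1), each = n), n, n)
  sqrt((rr - cen[1])^2 + (cc - cen[2])^2) <= r
}

test_that("anisotropic diffusion smooths noise but preserves edges", {
  ## constant image is a fixed point
  img <- matrix(5, 20, 20)
  expect_identical(anisotropic_diffusion(img), img)
  ## noise variance strictly decreases
  set.seed(1)
  noisy <- matrix(100 + rnorm(64 * 64, sd = 10), 64, 64)
  sm <- anisotropic_diffusion(noisy)
  expect_lt(var(as.numeric(sm)), var(as.numeric(noisy)))
  ## extrema are not amplified
  expect_gte(min(sm), min(noisy))
  expect_lte(max(sm), max(noisy))
  ## a sharp two-level step keeps its edge contrast
  step <- cbind(matrix(20, 40, 20), matrix(200, 40, 20))
  set.seed(2)
  stepn <- step + matrix(rnorm(40 * 40, sd = 2), 40, 40)
  sms <- anisotropic_diffusion(stepn)
  gcol <- abs(sms[, -1] - sms[, -ncol(sms)])
  edge_grad <- mean(gcol[, 19:20])
  bg_grad <- mean(gcol[, c(1:10, 30:39)])
  expect_gte(edge_grad, 10 * bg_grad)
  ## error paths
  expect_error(anisotropic_diffusion(img, iterations = 0), "positive")
})

test_that("FCM recovers a noise-free two-level image and matches its definition", {
  img <- matrix(c(20, 200), 10, 10)
  fit <- fcm_segment(img, C = 2, m = 2, tol = 1e-12)
  expect_lt(max(abs(fit$centers - c(20, 200))), 1e-6)
  expect_gte(min(apply(fit$memberships, 1, max)), 0.999)
  ## objective equals the direct double sum on the final (u, c)
  J_direct <- sum(fit$memberships^2 *
                    abs(outer(as.numeric(img), fit$centers, "-"))^2)
  expect_equal(tail(fit$J, 1), J_direct, tolerance = 1e-9)
  ## J non-increasing at every iteration
  expect_true(all(diff(fit$J) <= 1e-9 * fit$J[1]))
})

test_that("FCM with C = 10 converges monotonically on a phantom frame", {
  ph <- fixture_small_phantom()
  img <- round(anisotropic_diffusion(ph$images[[1]][[1]]))
  fit <- fcm_segment(img, C = 10, m = 2)
  expect_true(all(diff(fit$J) <= 1e-9 * fit$J[1]))
  expect_identical(fit$centers, sort(fit$centers))
  expect_equal(rowSums(fit$memberships), rep(1, length(img)), tolerance = 1e-12)
})

test_that("histogram-weighted and per-pixel FCM updates agree to 1e-9", {
  set.seed(3)
  img <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  f1 <- fcm_segment(img, C = 4, m = 2, tol = 1e-12, use_histogram = TRUE)
  f2 <- fcm_segment(img, C = 4, m = 2, tol = 1e-12, use_histogram = FALSE)
  expect_lt(max(abs(f1$centers - f2$centers)), 1e-9)
  expect_lt(max(abs(f1$memberships - f2$memberships)), 1e-9)
})

test_that("FCM near m = 1 reproduces hard k-means on well-separated data", {
  set.seed(4)
  x <- c(rnorm(50, 30, 2), rnorm(50, 180, 2))
  fit <- fcm_segment(matrix(x, 10, 10), C = 2, m = 1.05, tol = 1e-12)
  ## brute-force Lloyd oracle
  cen <- range(x)
  for (i in 1:100) {
    lab <- 1L + (abs(x - cen[2]) < abs(x - cen[1]))
    cen2 <- c(mean(x[lab == 1]), mean(x[lab == 2]))
    if (max(abs(cen2 - cen)) < 1e-12) break
    cen <- cen2
  }
  expect_identical(fit$hard, lab)
  expect_lt(max(abs(fit$centers - cen)), 0.5)
})

test_that("degenerate inputs are handled deterministically", {
  flat <- fcm_segment(matrix(7, 5, 5), C = 3)
  expect_true(flat$degenerate)
  ## a pixel exactly on two centres gets an equal membership split:
  ## symmetric two-point data, probe value at the midpoint
  fit <- fcm_segment(matrix(c(0, 10), 4, 4), C = 2, m = 2, tol = 1e-12)
  d <- abs(outer(5, fit$centers, "-"))
  expect_equal(d[1], d[2], tolerance = 1e-9)
})

test_that("lumen selection picks the hinted disk and flags far hints", {
  n <- 80
  img <- matrix(20, n, n)
  img[disk_mask(n, 16, c(30, 30))] <- 200
  img[disk_mask(n, 8, c(62, 62))] <- 200
  fit <- fcm_segment(img, C = 2)
  ## hint on the larger disk: mask covers it and not the smaller one
  mask <- select_lumen_region(fit, img, c(30, 30))
  truth <- disk_mask(n, 16, c(30, 30))
  expect_gte(dice_coefficient(mask, truth), 0.98)
  expect_false(any(mask & disk_mask(n, 8, c(62, 62))))
  ## zero-noise single disk: near-perfect overlap
  img2 <- matrix(20, n, n)
  img2[disk_mask(n, 15)] <- 200
  fit2 <- fcm_segment(img2, C = 2)
  mask2 <- select_lumen_region(fit2, img2, c((n - 1) / 2, (n - 1) / 2))
  expect_gte(dice_coefficient(mask2, disk_mask(n, 15)), 0.98)
  ## hint in empty background far from any region
  expect_error(select_lumen_region(fit2, img2, c(3, 3), search_radius = 10),
               "lumen not found")
})

test_that("trace extraction measures circles and squares correctly and filters artifacts", {
  ## filled disk: near-unit circularity, perimeter within 2% of 2*pi*r
  m <- disk_mask(101, 30)
  tr <- extract_and_filter_traces(m)
  expect_s3_class(tr, "lv_trace")
  expect_gte(tr$circularity, 0.98)
  expect_lt(abs(polygon_perimeter(tr$points) - 2 * pi * 30) / (2 * pi * 30), 0.02)
  ## filled square: circularity pi/4 within rasterization tolerance
  sq <- matrix(FALSE, 60, 60); sq[15:45, 15:45] <- TRUE
  trs <- extract_and_filter_traces(sq, min_circularity = 0, smooth_window = 1)
  expect_equal(trs$circularity, pi / 4, tolerance = 0.02)
  ## crescent artifact with low circularity is rejected with the reason
  cres <- disk_mask(80, 25) & !disk_mask(80, 22, c(33, 39.5))
  trc <- extract_and_filter_traces(cres, min_circularity = 0.6)
  expect_s3_class(trc, "lv_trace_rejected")
  expect_match(trc$reason, "circularity")
  ## empty mask errors
  expect_error(extract_and_filter_traces(matrix(FALSE, 5, 5)), "empty mask")
})

test_that("snake locks onto a noise-free disk edge", {
  n <- 101; r <- 30
  cen <- c(50, 50)
  img <- matrix(20, n, n)
  img[disk_mask(n, r, cen)] <- 200
  img <- anisotropic_diffusion(img, iterations = 2)
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  on_edge <- cbind(cen[1] + r * sin(th), cen[2] + r * cos(th))
  rms_r <- function(tr) {
    d <- sqrt((tr$points[, 1] - cen[1])^2 + (tr$points[, 2] - cen[2])^2)
    sqrt(mean((d - r)^2))
  }
  tr0 <- structure(list(points = on_edge), class = "lv_trace")
  expect_lt(rms_r(snake_refine(tr0, img)), 0.5)
  ## initialization offset 3 px outward still converges to within 1 px RMS
  off <- cbind(cen[1] + (r + 3) * sin(th), cen[2] + (r + 3) * cos(th))
  tr1 <- structure(list(points = off), class = "lv_trace")
  expect_lt(rms_r(snake_refine(tr1, img, iterations = 200)), 1)
})

test_that("with zero image force the snake shrinks monotonically", {
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  pts <- cbind(50 + 20 * sin(th), 50 + 20 * cos(th))
  tr <- structure(list(points = pts), class = "lv_trace")
  img <- matrix(0, 101, 101)
  per <- vapply(c(5, 20, 60), function(it)
    polygon_perimeter(snake_refine(tr, img, edge_weight = 0,
                                   iterations = it)$points), 1)
  expect_true(all(diff(c(polygon_perimeter(pts), per)) < 0))
})

test_that("trace smoothing averages along and across contours", {
  ## collinear points on a straight segment are unchanged
  line <- cbind(seq(0, 10, length.out = 20), seq(0, 20, length.out = 20))
  trl <- structure(list(points = line), class = "lv_trace")
  sm <- smooth_traces(list(trl, trl, trl), window_along = 1, window_across = 3)
  expect_equal(sm[[2]]$points, line)
  ## a single perturbed point is pulled back by at least half
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  circ <- cbind(30 + 10 * sin(th), 30 + 10 * cos(th))
  pert <- circ; pert[5, ] <- pert[5, ] + c(2, 0)
  smp <- smooth_traces(list(structure(list(points = pert), class = "lv_trace")),
                       window_along = 5, window_across = 1)
  resid <- function(p) sqrt(sum((p[5, ] - circ[5, ])^2))
  expect_lt(resid(smp[[1]]$points), 0.5 * resid(pert))
  ## area change stays small
  expect_lt(abs(abs(polygon_area(smp[[1]]$points)) - abs(polygon_area(pert))) /
              abs(polygon_area(pert)), 0.02)
  ## degenerate inputs
  expect_warning(smooth_traces(list(trl), window_across = 3), "single trace")
  trbad <- structure(list(points = line[1:10, ]), class = "lv_trace")
  expect_error(smooth_traces(list(trl, trbad)), "common point count")
})

test_that("phantom segmentation yields simple CCW traces and high Dice", {
  ph <- fixture_small_phantom()
  seg <- segment_cine_stack(lapply(ph$images, function(s) s[1:2]),
                            center_hint = ph$center_px)
  for (s in seq_along(seg$traces)) for (p in seq_along(seg$traces[[s]])) {
    tr <- seg$traces[[s]][[p]]
    expect_s3_class(tr, "lv_trace")
    xy <- tr$points[, c(2, 1)]
    expect_gt(polygon_area(xy), 0)               # CCW orientation
    expect_true(lvflow:::polygon_is_simple(tr$points))
  }
  dc <- segmentation_dice(seg, lapply(ph$masks, function(s) s[1:2]))
  expect_gte(min(dc), 0.95)
})

test_that("manual traces round-trip through the CSV sidecar format", {
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  pts <- cbind(row = 40 + 12 * sin(th), col = 50 + 15 * cos(th))
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(row = pts[, 1], col = pts[, 2]), f, row.names = FALSE)
  trs <- read_traces_csv(f)
  expect_length(trs, 1)
  expect_equal(unname(trs[[1]]$points), unname(pts), tolerance = 1e-12)
  expect_gt(polygon_area(trs[[1]]$points[, c(2, 1)]), 0)
})
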