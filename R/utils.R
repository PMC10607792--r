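#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx coef dist kmeans lm rnorm runif sd var setNames
#' @importFrom utils head tail read.csv write.csv packageVersion
#' @importFrom grDevices contourLines dev.off png
#' @importFrom graphics abline axis legend lines par plot points
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Run code with a private RNG stream: global .Random.seed is left untouched.
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Signed area of a closed polygon (shoelace formula)
#'
#' Positive for counter-clockwise vertex order in a right-handed (x up-right,
#' y up) frame. The polygon is closed implicitly (last vertex joins the first).
#'
#' @param pts two-column matrix of vertices (x, y).
#' @return signed area, in squared input units.
#' @export
polygon_area <- function(pts) {
  pts <- as.matrix(pts)
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_centroid <- function(pts) {
  pts <- as.matrix(pts)
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100) return(colMeans(pts))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

polygon_perimeter <- function(pts, closed = TRUE) {
  pts <- as.matrix(pts)
  d <- diff(if (closed) rbind(pts, pts[1, , drop = FALSE]) else pts)
  sum(sqrt(rowSums(d^2)))
}

#' Circularity of a closed polygon
#'
#' \eqn{4\pi A / P^2}; equals 1 for a circle, \eqn{\pi/4} for a square.
#' @param pts two-column vertex matrix (closed implicitly).
#' @return circularity in (0, 1] for simple polygons.
#' @export
circularity <- function(pts) {
  4 * pi * abs(polygon_area(pts)) / polygon_perimeter(pts)^2
}

## O(n^2) segment-pair test; adequate for contour sizes used here (<= ~512).
polygon_is_simple <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3) return(FALSE)
  p <- rbind(pts, pts[1, , drop = FALSE])
  a1 <- p[1:n, , drop = FALSE]; a2 <- p[2:(n + 1), , drop = FALSE]
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]           # skip segments sharing a vertex
    if (!length(js)) next
    d1 <- cross2(a1[i, 1], a1[i, 2], a2[i, 1], a2[i, 2], a1[js, 1], a1[js, 2])
    d2 <- cross2(a1[i, 1], a1[i, 2], a2[i, 1], a2[i, 2], a2[js, 1], a2[js, 2])
    d3 <- cross2(a1[js, 1], a1[js, 2], a2[js, 1], a2[js, 2],
                 rep(a1[i, 1], length(js)), rep(a1[i, 2], length(js)))
    d4 <- cross2(a1[js, 1], a1[js, 2], a2[js, 1], a2[js, 2],
                 rep(a2[i, 1], length(js)), rep(a2[i, 2], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

## Resample a polyline to n points, uniform in arclength.
## closed = TRUE treats pts as a closed loop and returns n points (no repeat).
resample_polyline <- function(pts, n, closed = FALSE) {
  pts <- as.matrix(pts)
  if (closed) pts <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L <= 0) stopf("degenerate polyline: zero total length")
  target <- if (closed) seq(0, L, length.out = n + 1)[1:n] else seq(0, L, length.out = n)
  out <- vapply(seq_len(ncol(pts)),
                function(k) approx(s, pts[, k], xout = target, ties = "ordered")$y,
                numeric(length(target)))
  matrix(out, ncol = ncol(pts))
}

## Circular (along-contour) moving average with odd window w.
circular_moving_average <- function(x, w) {
  if (w <= 1) return(x)
  if (w %% 2 == 0) stopf("smoothing window must be odd, got %d", w)
  n <- length(x)
  h <- (w - 1) / 2
  idx <- outer(seq_len(n), -h:h, "+")
  idx <- ((idx - 1) %% n) + 1
  rowMeans(matrix(x[idx], nrow = n))
}

#' Dice overlap coefficient between two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}.
#' @param a,b logical or 0/1 matrices of equal shape.
#' @return Dice coefficient in [0, 1]; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stopf("mask shapes differ")
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
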