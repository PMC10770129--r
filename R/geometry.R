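#' Polygon utilities on the 0.5 um/px pixel grid
#'
#' Polygons are two-column matrices of (x, y) vertices, 0-based, y-down, in
#' pixel units at full resolution. Pixel (row r, col c) has its center at
#' (c + 0.5, r + 0.5); a pixel belongs to a polygon iff its center is inside
#' under the even-odd rule.
#'
#' @param poly two-column numeric matrix of vertices (not closed).
#' @return `polygon_area`: signed-area magnitude (shoelace) in px^2;
#'   `polygon_centroid`: length-2 numeric (x, y); `polygon_pixels`: integer
#'   vector of 1-based linear indices into an `height` x `width` matrix.
#' @keywords internal
#' @name geometry
NULL

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

polygon_pixels <- function(poly, height, width) {
  fill_polygon_cpp(as.numeric(poly[, 1]), as.numeric(poly[, 2]),
                   as.integer(height), as.integer(width))
}

# Perturbed-ellipse polygon: irregular follicle-like contour with
# `n_points` control points and radial jitter up to `jitter` (fraction).
# Consumes the caller's RNG stream.
perturbed_ellipse <- function(cx, cy, rx, ry, n_points = NULL, jitter = 0.2) {
  if (is.null(n_points)) n_points <- sample(8:16, 1)
  theta <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  f <- 1 + runif(n_points, -jitter, jitter)
  cbind(cx + rx * f * cos(theta), cy + ry * f * sin(theta))
}

# Scale a polygon about its centroid by factor f.
scale_polygon <- function(poly, f) {
  ctr <- polygon_centroid(poly)
  cbind(ctr[1] + f * (poly[, 1] - ctr[1]), ctr[2] + f * (poly[, 2] - ctr[2]))
}
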