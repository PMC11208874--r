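# Low-level planar geometry helpers shared by the contour, hull and
# architecture code. All polygons are n x 2 matrices of (x, y) vertices,
# implicitly closed (first vertex != last).

#' Signed shoelace area of a closed polygon
#'
#' Positive for the vertex orientation produced by [mask_to_contour()]
#' (interior kept on a consistent side in image coordinates, y down).
#'
#' @param poly n x 2 numeric matrix of vertices, implicitly closed.
#' @return Signed area in squared coordinate units.
#' @keywords internal
poly_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

poly_area <- function(poly) abs(poly_signed_area(poly))

poly_perimeter <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(sqrt((xn - x)^2 + (yn - y)^2))
}

#' Area-weighted centroid of a simple polygon
#' @keywords internal
poly_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

#' Test points against a polygon (boundary counts as inside)
#'
#' Vectorised crossing-number test with an explicit on-segment check so
#' that polygon vertices and points lying on edges are classified inside.
#'
#' @param px,py point coordinates.
#' @param poly n x 2 polygon matrix.
#' @param eps tolerance for the on-boundary test.
#' @return logical vector.
#' @keywords internal
points_in_polygon <- function(px, py, poly, eps = 1e-9) {
  vx <- poly[, 1]; vy <- poly[, 2]
  vxn <- c(vx[-1], vx[1]); vyn <- c(vy[-1], vy[1])
  n <- length(px)
  inside <- logical(n)
  for (i in seq_len(n)) {
    x <- px[i]; y <- py[i]
    # on-boundary check: point within eps of any edge segment
    dx <- vxn - vx; dy <- vyn - vy
    len2 <- dx^2 + dy^2
    t <- ifelse(len2 > 0, ((x - vx) * dx + (y - vy) * dy) / len2, 0)
    t <- pmin(1, pmax(0, t))
    d2 <- (vx + t * dx - x)^2 + (vy + t * dy - y)^2
    if (any(d2 <= eps^2)) { inside[i] <- TRUE; next }
    crosses <- ((vy > y) != (vyn > y)) &
      (x < vx + (y - vy) * (vxn - vx) / (vyn - vy))
    inside[i] <- (sum(crosses) %% 2L) == 1L
  }
  inside
}

# Does segment (a1, a2) properly intersect any of the segments given by
# (bx1, by1)-(bx2, by2)? Shared endpoints do not count. Vectorised over b.
segments_intersect_any <- function(a1, a2, bx1, by1, bx2, by2, eps = 1e-12) {
  d1x <- a2[1] - a1[1]; d1y <- a2[2] - a1[2]
  d2x <- bx2 - bx1;     d2y <- by2 - by1
  denom <- d1x * d2y - d1y * d2x
  ex <- bx1 - a1[1]; ey <- by1 - a1[2]
  t <- (ex * d2y - ey * d2x) / denom
  u <- (ex * d1y - ey * d1x) / denom
  ok <- abs(denom) > eps & t > eps & t < 1 - eps & u > eps & u < 1 - eps
  any(ok, na.rm = TRUE)
}
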