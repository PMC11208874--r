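# Per-object geometry and color features.

#' Geometric metrics of a closed contour
#'
#' Length is the maximum Feret diameter (largest pairwise vertex
#' distance); width is the extent along the direction perpendicular to
#' the Feret axis; aspect ratio is width / length, so elongated objects
#' score low. Millimetre fields are filled when a scale is supplied.
#'
#' @param contour n x 2 vertex matrix, implicitly closed.
#' @param scale_mm_per_px optional scalar scale.
#' @return list of class `shape_metrics`: `area`, `perimeter`, `length`,
#'   `width`, `aspect_ratio`, `centroid`, `perimeter_area_ratio`, and
#'   `area_mm2`/`perimeter_mm`/`length_mm`/`width_mm` when scaled.
#' @export
contour_metrics <- function(contour, scale_mm_per_px = NULL) {
  if (!is.matrix(contour) || nrow(contour) < 3L)
    stop("degenerate contour: need at least 3 vertices")
  area <- poly_area(contour)
  if (area <= 0) stop("degenerate contour: zero area")
  per <- poly_perimeter(contour)
  hull <- contour[grDevices::chull(contour[, 1], contour[, 2]), , drop = FALSE]
  d <- as.matrix(stats::dist(hull))
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  len <- d[ij[1], ij[2]]
  axis <- hull[ij[2], ] - hull[ij[1], ]
  axis <- axis / sqrt(sum(axis^2))
  perp <- c(-axis[2], axis[1])
  proj <- contour %*% perp
  wid <- max(proj) - min(proj)
  out <- list(area = area, perimeter = per, length = len, width = wid,
              aspect_ratio = min(1, wid / len),
              centroid = poly_centroid(contour),
              perimeter_area_ratio = per / area)
  if (!is.null(scale_mm_per_px)) {
    s <- scale_mm_per_px
    out$area_mm2 <- area * s^2
    out$perimeter_mm <- per * s
    out$length_mm <- len * s
    out$width_mm <- wid * s
  }
  class(out) <- "shape_metrics"
  out
}

#' Median RGB color over mask pixels
#'
#' @param mask binary matrix, `rle_mask`, or `mask_record`.
#' @param image (h x w x 3) array; values in [0, 1] are rescaled to 0-255.
#' @return named numeric `c(r, g, b)` of per-channel medians on 0-255.
#' @export
median_color <- function(mask, image) {
  m <- as_binary_matrix(mask)
  if (!any(m == 1L)) stop("empty mask")
  if (length(dim(image)) != 3L || any(dim(image)[1:2] != dim(m)))
    stop("mask and image dimensions differ")
  if (max(image) <= 1) image <- image * 255
  idx <- which(m == 1L)
  npx <- prod(dim(m))
  c(r = stats::median(image[idx]),
    g = stats::median(image[idx + npx]),
    b = stats::median(image[idx + 2L * npx]))
}

#' Circularity of a contour on an outline-smoothed perimeter
#'
#' Raw pixel-edge perimeters of rasterized disks are staircase lengths
#' (about 8r rather than 2*pi*r), which deflates the isoperimetric ratio.
#' Circularity is therefore computed as 4*pi*A/P^2 with the perimeter
#' taken from a 10-harmonic elliptical-Fourier resampling of the outline.
#'
#' @param contour n x 2 vertex matrix.
#' @return circularity in (0, 1] (1 = perfect circle), capped at 1.
#' @export
contour_circularity <- function(contour) {
  sm <- efd_reconstruct(
    efd_coefficients(contour, n_harmonics = 10,
                     normalize_scale = FALSE, normalize_rotation = FALSE),
    n_points = 200)
  min(1, 4 * pi * poly_area(sm) / poly_perimeter(sm)^2)
}
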