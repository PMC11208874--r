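# Cluster-level architecture descriptors computed from berry positions
# and masks: ECDF position profiles with symmetry classes, concave hulls
# with compactness, and cross-cluster outline shape PCA.

#' ECDF profile of berry positions along an image axis
#'
#' Berry centroids are projected on the axis, shifted to start at 0,
#' scaled so the maximum is 100, and the empirical cumulative
#' distribution is sampled at 100 evenly spaced normalized coordinates.
#' The y axis runs from the peduncle (top of the image) to the cluster
#' tip.
#'
#' @param berries n x 2 centroid matrix, a list of berry records, or a
#'   data.frame with `centroid_x`/`centroid_y`.
#' @param axis `"x"` or `"y"`.
#' @return object of class `ecdf_profile`: `axis`,
#'   `normalized_coordinates` (100 values on [0, 100]),
#'   `cumulative_fraction`, and `quantile_at_25/50/75` (cumulative
#'   fraction at normalized coordinate 25/50/75).
#' @export
ecdf_profile <- function(berries, axis = c("x", "y")) {
  axis <- match.arg(axis)
  cent <- berry_centroids(berries)
  v <- cent[, if (axis == "x") 1 else 2]
  if (length(v) < 2L || diff(range(v)) == 0)
    stop("need >= 2 berries with distinct positions to scale the profile")
  v <- (v - min(v)) * 100 / (max(v) - min(v))
  F <- stats::ecdf(v)
  coords <- seq(0, 100, length.out = 100)
  structure(list(axis = axis, normalized_coordinates = coords,
                 cumulative_fraction = F(coords),
                 quantile_at_25 = F(25), quantile_at_50 = F(50),
                 quantile_at_75 = F(75), n = length(v)),
            class = "ecdf_profile")
}

berry_centroids <- function(berries) {
  if (is.matrix(berries)) return(berries)
  if (is.data.frame(berries))
    return(cbind(berries$centroid_x, berries$centroid_y))
  t(vapply(berries, function(r) ensure_metrics(r)$metrics$centroid,
           numeric(2)))
}

#' Classify a profile into symmetry classes
#'
#' Thresholds on the cumulative fraction at normalized coordinates 25,
#' 50 and 75: skewed one way when q25 > 0.3 and q75 > 0.8; skewed the
#' other way when q25 < 0.2 and q75 < 0.7; symmetric when q25 in
#' [0.2, 0.3], q50 in [0.45, 0.55] and q75 in [0.7, 0.8]; otherwise
#' `other`.
#'
#' @param profile an [ecdf_profile()].
#' @return one of `"skew_left"`, `"skew_right"`, `"symmetric"`, `"other"`.
#' @export
classify_symmetry <- function(profile) {
  q25 <- profile$quantile_at_25; q50 <- profile$quantile_at_50
  q75 <- profile$quantile_at_75
  if (q25 > 0.3 && q75 > 0.8) return("skew_left")
  if (q25 < 0.2 && q75 < 0.7) return("skew_right")
  if (q25 >= 0.2 && q25 <= 0.3 && q50 >= 0.45 && q50 <= 0.55 &&
      q75 >= 0.7 && q75 <= 0.8) return("symmetric")
  "other"
}

#' Concave hull of a cluster's berry outlines
#'
#' k-nearest-neighbour concave hull over the union of berry contour
#' vertices. `concavity` maps to the neighbour count: small values trace
#' the point cloud tightly (sinuses between wings preserved), large
#' values smooth toward the convex hull, which is the limit. The hull is
#' grown until it contains every input vertex.
#'
#' @param berries list of berry records, list of contour matrices, or an
#'   n x 2 point matrix.
#' @param concavity detail parameter (>= 3 effective); larger is
#'   smoother.
#' @param max_points contour vertices are thinned to about this many
#'   points before hull construction (containment is still enforced
#'   against all of them).
#' @return object of class `hull_shape`: `polygon`, `concavity`, `area`,
#'   `perimeter`, `length` (y extent), `width` (x extent),
#'   `aspect_ratio` (width/length).
#' @export
concave_hull <- function(berries, concavity = 8, max_points = 400) {
  pts <- hull_input_points(berries)
  pts <- unique(pts)
  if (nrow(pts) < 3L) stop("need >= 3 distinct points for a hull")
  if (stats::sd(pts[, 1]) < 1e-9 && stats::sd(pts[, 2]) < 1e-9 ||
      collinear_points(pts))
    stop("degenerate input: points are collinear")
  sub <- pts
  if (nrow(sub) > max_points)
    sub <- sub[seq(1, nrow(sub), length.out = max_points), , drop = FALSE]
  k <- max(3L, as.integer(round(concavity)))
  repeat {
    poly <- knn_concave_hull(sub, k)
    if (!is.null(poly) &&
        all(points_in_polygon(pts[, 1], pts[, 2], poly, eps = 1e-7))) break
    k <- k + max(2L, k %/% 2L)
    if (k >= nrow(sub)) {
      poly <- sub[grDevices::chull(sub[, 1], sub[, 2]), , drop = FALSE]
      break
    }
  }
  hull_metrics(poly, concavity)
}

hull_input_points <- function(berries) {
  if (is.matrix(berries)) return(berries[, 1:2, drop = FALSE])
  if (is.list(berries) && length(berries) && is.matrix(berries[[1]]))
    return(do.call(rbind, berries))
  do.call(rbind, lapply(berries, function(r) ensure_contour(r)$contour))
}

collinear_points <- function(pts) {
  p <- sweep(pts, 2, colMeans(pts))
  sv <- svd(p)$d
  sv[2] < 1e-9 * max(sv[1], 1)
}

hull_metrics <- function(poly, concavity) {
  structure(list(polygon = poly, concavity = concavity,
                 area = poly_area(poly), perimeter = poly_perimeter(poly),
                 length = diff(range(poly[, 2])),
                 width = diff(range(poly[, 1])),
                 aspect_ratio = diff(range(poly[, 1])) /
                   diff(range(poly[, 2]))),
            class = "hull_shape")
}

# Moreira-Santos k-nearest-neighbour concave hull. Returns NULL when no
# simple closed polygon is found at this k.
knn_concave_hull <- function(pts, k) {
  n <- nrow(pts)
  if (k >= n) return(pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE])
  start <- which.max(pts[, 2])  # lowest point on screen (max y)
  used <- logical(n)
  hull_idx <- start
  used[start] <- TRUE
  cur <- start
  prev_angle <- 0  # incoming direction, pointing at current point
  step <- 0L
  repeat {
    step <- step + 1L
    if (step > 4L * n) return(NULL)
    if (step >= 3L) used[start] <- FALSE  # allow closing
    d2 <- (pts[, 1] - pts[cur, 1])^2 + (pts[, 2] - pts[cur, 2])^2
    d2[used] <- Inf; d2[cur] <- Inf
    cand <- order(d2)[seq_len(min(k, sum(is.finite(d2))))]
    cand <- cand[is.finite(d2[cand])]
    if (length(cand) == 0L) return(NULL)
    ang <- atan2(pts[cand, 2] - pts[cur, 2], pts[cand, 1] - pts[cur, 1])
    # largest right-hand turn relative to the incoming direction
    turn <- (prev_angle + pi - ang) %% (2 * pi)
    cand <- cand[order(-turn)]
    nxt <- NULL
    for (cd in cand) {
      if (length(hull_idx) >= 2L) {
        hx <- pts[hull_idx, 1]; hy <- pts[hull_idx, 2]
        m <- length(hull_idx)
        lim <- if (cd == start) m - 2L else m - 1L
        if (lim >= 1L &&
            segments_intersect_any(pts[cur, ], pts[cd, ],
                                   hx[seq_len(lim)], hy[seq_len(lim)],
                                   hx[seq_len(lim) + 1L],
                                   hy[seq_len(lim) + 1L])) next
      }
      nxt <- cd; break
    }
    if (is.null(nxt)) return(NULL)
    if (nxt == start) break
    hull_idx <- c(hull_idx, nxt)
    used[nxt] <- TRUE
    prev_angle <- atan2(pts[nxt, 2] - pts[cur, 2], pts[nxt, 1] - pts[cur, 1])
    cur <- nxt
  }
  if (length(hull_idx) < 3L) return(NULL)
  pts[hull_idx, , drop = FALSE]
}

#' Cluster compactness
#'
#' Ratio between the summed berry areas and the concave-hull area; dense
#' clusters approach 1, loose or winged clusters score low.
#'
#' @param berry_areas numeric vector of berry areas (same units as the
#'   hull), or a list of berry records.
#' @param hull a [concave_hull()] result.
#' @return unitless ratio.
#' @export
compactness <- function(berry_areas, hull) {
  if (is.list(berry_areas) && !is.numeric(berry_areas))
    berry_areas <- vapply(berry_areas, function(r)
      ensure_metrics(r)$metrics$area, numeric(1))
  if (hull$area <= 0) stop("hull area is zero")
  sum(berry_areas) / hull$area
}

#' PCA of cluster outline shape across clusters
#'
#' Each hull outline is encoded by elliptical Fourier coefficients with
#' translation and scale removed but rotation retained (clusters share a
#' canonical hanging orientation), and a PCA is fit on the flattened
#' coefficients.
#'
#' @param hulls list of `hull_shape` (or polygon matrices).
#' @param n_harmonics harmonics per outline.
#' @return object of class `shape_pca`: `scores` (clusters x
#'   components), `explained_variance_fraction` (sums to 1), `loadings`,
#'   `n_harmonics`.
#' @export
shape_pca <- function(hulls, n_harmonics = 10) {
  if (length(hulls) < 3L) stop("need >= 3 hulls for a shape PCA")
  feats <- t(vapply(hulls, function(h) {
    poly <- if (inherits(h, "hull_shape")) h$polygon else h
    efd_flatten(efd_coefficients(poly, n_harmonics = n_harmonics,
                                 normalize_scale = TRUE,
                                 normalize_rotation = FALSE))
  }, numeric(4 * n_harmonics)))
  pc <- stats::prcomp(feats, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  structure(list(scores = pc$x,
                 explained_variance_fraction = v / sum(v),
                 loadings = pc$rotation,
                 n_harmonics = n_harmonics),
            class = "shape_pca")
}

#' Architecture descriptor table for a set of cluster views
#'
#' One row per (cluster, angle): compactness, hull metrics, x/y profile
#' quantiles and symmetry classes.
#'
#' @param views named list; each element a list with `berries` (berry
#'   records) and optional `cluster_id`/`angle`.
#' @param concavity hull detail parameter.
#' @return data.frame.
#' @export
architecture_table <- function(views, concavity = 8) {
  rows <- lapply(views, function(v) {
    b <- v$berries
    hull <- concave_hull(b, concavity)
    px <- ecdf_profile(b, "x"); py <- ecdf_profile(b, "y")
    data.frame(cluster_id = v$cluster_id %||% NA_character_,
               angle = v$angle %||% NA_real_,
               n_berries = length(b),
               compactness = compactness(b, hull),
               hull_area = hull$area, hull_perimeter = hull$perimeter,
               hull_length = hull$length, hull_width = hull$width,
               hull_aspect = hull$aspect_ratio,
               x_q25 = px$quantile_at_25, x_q50 = px$quantile_at_50,
               x_q75 = px$quantile_at_75,
               y_q25 = py$quantile_at_25, y_q50 = py$quantile_at_50,
               y_q75 = py$quantile_at_75,
               x_symmetry = classify_symmetry(px),
               y_symmetry = classify_symmetry(py))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
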