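# Reduction of raw generator masks to true berry masks. Stages follow the
# processing order used in practice: overlap-based merged-mask removal,
# relative geometric filters, then iterative EFD + PCA outlier rejection.

#' Filtering configuration
#'
#' Geometric thresholds are multiples of per-image medians so the filter
#' is scale-free; absolute fallback bounds apply when a scene has fewer
#' than 3 records.
#'
#' @param containment_threshold overlap of a child with a candidate
#'   merged mask, as a fraction of the child's area, above which the
#'   child supports removal.
#' @param min_children children required to call a mask merged.
#' @param area_bounds keep masks whose area lies within these multiples
#'   of the median area.
#' @param aspect_min minimum width/length aspect ratio.
#' @param perimeter_area_max maximum perimeter-to-area ratio, as a
#'   multiple of the median ratio.
#' @param max_centroid_distance maximum distance from the cluster
#'   centroid, in multiples of the cluster radius.
#' @param pca_rounds,pca_n_components,pca_sd_threshold EFD + PCA outlier
#'   loop: number of rounds, leading components inspected, and the
#'   per-component score cut in standard deviations.
#' @param pca_min_deviation minimum effect size for an outlier call:
#'   besides exceeding the score threshold, a mask's flattened
#'   normalized coefficients must lie at least this far (Euclidean
#'   distance, in units of the unit outline scale) from the
#'   coefficient-wise median shape. Statistical extremeness alone on a
#'   tight axis does not make an outline a non-berry; this keeps
#'   ordinary berry variation (partially occluded crescents included)
#'   while gross shapes -- rachis bits, stars, merged blobs -- are far
#'   outside the berry morphospace. It is also what stops the iteration
#'   once only berries remain.
#' @param abs_area_bounds absolute pixel-area fallback for tiny scenes.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(containment_threshold = 0.8, min_children = 2,
                          area_bounds = c(0.2, 5.0), aspect_min = 0.4,
                          perimeter_area_max = 3.0,
                          max_centroid_distance = 2.0,
                          pca_rounds = 5, pca_n_components = 10,
                          pca_sd_threshold = 2.0, pca_min_deviation = 0.25,
                          abs_area_bounds = c(30, 1e5)) {
  cfg <- list(containment_threshold = containment_threshold,
              min_children = min_children, area_bounds = area_bounds,
              aspect_min = aspect_min,
              perimeter_area_max = perimeter_area_max,
              max_centroid_distance = max_centroid_distance,
              pca_rounds = pca_rounds,
              pca_n_components = pca_n_components,
              pca_sd_threshold = pca_sd_threshold,
              pca_min_deviation = pca_min_deviation,
              abs_area_bounds = abs_area_bounds)
  stopifnot(all(unlist(cfg) >= 0), pca_rounds >= 1)
  class(cfg) <- "filter_config"
  cfg
}

#' Overlap measures between two masks
#'
#' @param a,b masks on the same image grid (binary matrix, `rle_mask`,
#'   or `mask_record`).
#' @return named numeric: `iou` = |A&B|/|A|B|union, `containment` =
#'   |A&B|/min(|A|,|B|); both symmetric, in [0, 1].
#' @export
pairwise_overlap <- function(a, b) {
  ma <- as_binary_matrix(a); mb <- as_binary_matrix(b)
  if (!any(ma == 1L) || !any(mb == 1L)) stop("empty mask")
  if (any(dim(ma) != dim(mb))) stop("masks are on different image grids")
  inter <- sum(ma == 1L & mb == 1L)
  na <- sum(ma); nb <- sum(mb)
  c(iou = inter / (na + nb - inter), containment = inter / min(na, nb))
}

# Pixel index sets for all records, with a bbox prefilter helper.
record_pixel_sets <- function(records) {
  lapply(records, function(r) which(decode_rle(r$mask) == 1L))
}

bbox_overlaps <- function(b1, b2) {
  !(b1[1] + b1[3] <= b2[1] || b2[1] + b2[3] <= b1[1] ||
    b1[2] + b1[4] <= b2[2] || b2[2] + b2[4] <= b1[2])
}

#' Remove masks that cover two or more berries
#'
#' A mask is called merged and removed when at least `min_children`
#' smaller masks each lie almost entirely (containment above threshold)
#' inside it: a mask spanning two berries overlaps each berry's own mask
#' with high containment while being larger than either.
#'
#' @param records list of `mask_record`s from one image.
#' @param config a [filter_config()].
#' @return list with `kept`, `removed`, and `removals` (data.frame of
#'   id, stage, reason).
#' @export
remove_multiberry_masks <- function(records, config = filter_config()) {
  n <- length(records)
  if (n == 0L)
    return(list(kept = records, removed = list(),
                removals = empty_removals()))
  px <- record_pixel_sets(records)
  areas <- vapply(px, length, integer(1))
  drop <- logical(n); reason <- character(n)
  for (i in seq_len(n)) {
    kids <- character(0)
    for (j in seq_len(n)) {
      if (j == i || areas[j] >= areas[i]) next
      if (!bbox_overlaps(records[[i]]$bbox, records[[j]]$bbox)) next
      inter <- length(intersect(px[[i]], px[[j]]))
      if (inter / areas[j] >= config$containment_threshold)
        kids <- c(kids, record_id(records[[j]], j))
    }
    if (length(kids) >= config$min_children) {
      drop[i] <- TRUE
      reason[i] <- paste0("contains:", paste(kids, collapse = "+"))
    }
  }
  split_records(records, drop, "overlap", reason)
}

#' Geometric filtering of non-berry masks
#'
#' Removes masks whose area, aspect ratio or perimeter-to-area ratio is
#' far from the per-image median (berries dominate the records, so
#' medians characterise berries), or whose centroid lies far outside the
#' cluster. Each removal carries a reason: `area`, `aspect`,
#' `perimeter_area` or `distance`.
#'
#' @param records list of `mask_record`s (metrics computed on the fly and
#'   cached on the records).
#' @param config a [filter_config()].
#' @param cluster_centroid optional (x, y); defaults to the
#'   component-wise median of record centroids.
#' @return list with `kept`, `removed`, `removals`.
#' @export
geometric_filter <- function(records, config = filter_config(),
                             cluster_centroid = NULL) {
  n <- length(records)
  if (n == 0L)
    return(list(kept = records, removed = list(),
                removals = empty_removals()))
  records <- lapply(records, ensure_metrics)
  areas <- vapply(records, function(r) r$metrics$area, numeric(1))
  aspects <- vapply(records, function(r) r$metrics$aspect_ratio, numeric(1))
  pa <- vapply(records, function(r) r$metrics$perimeter_area_ratio, numeric(1))
  cents <- t(vapply(records, function(r) r$metrics$centroid, numeric(2)))

  if (n < 3L) {
    warning("fewer than 3 records: using absolute fallback area bounds")
    lo <- config$abs_area_bounds[1]; hi <- config$abs_area_bounds[2]
    pa_max <- Inf
  } else {
    med_area <- stats::median(areas)
    lo <- config$area_bounds[1] * med_area
    hi <- config$area_bounds[2] * med_area
    pa_max <- config$perimeter_area_max * stats::median(pa)
  }
  if (is.null(cluster_centroid))
    cluster_centroid <- c(stats::median(cents[, 1]), stats::median(cents[, 2]))
  # elliptical distance in units of the cluster's own robust extent:
  # clusters hang vertically and are elongated, so each axis is scaled
  # by 1.4x the upper quartile of |offset| on that axis (berries
  # dominate the records, so the quartile ignores far distractors)
  dx <- cents[, 1] - cluster_centroid[1]
  dy <- cents[, 2] - cluster_centroid[2]
  sx <- 1.4 * stats::quantile(abs(dx), 0.75, names = FALSE)
  sy <- 1.4 * stats::quantile(abs(dy), 0.75, names = FALSE)
  sx <- max(sx, 0.1 * sy, 1); sy <- max(sy, 0.1 * sx, 1)
  d <- sqrt((dx / sx)^2 + (dy / sy)^2)
  d_max <- if (n >= 3L) config$max_centroid_distance else Inf

  reason <- character(n)
  reason[d > d_max] <- "distance"
  reason[pa > pa_max] <- "perimeter_area"
  reason[aspects < config$aspect_min] <- "aspect"
  reason[areas < lo | areas > hi] <- "area"
  split_records(records, reason != "", "geometric", reason)
}

#' Iterative EFD + PCA shape-outlier removal
#'
#' Per round: elliptical Fourier coefficients (translation and scale
#' removed, rotation retained) are recomputed on the currently kept
#' masks, a PCA is fit on the flattened coefficients, and any mask whose
#' score exceeds `pca_sd_threshold` standard deviations on any of the
#' first `pca_n_components` components is removed. Stops early when a
#' round removes nothing; zero-variance components are skipped.
#'
#' @param records list of `mask_record`s.
#' @param config a [filter_config()].
#' @return list with `kept`, `removed`, `removals`, and `rounds`
#'   (data.frame of round, n_before, n_removed).
#' @export
efd_pca_outlier_removal <- function(records, config = filter_config()) {
  n <- length(records)
  if (n < config$pca_n_components + 2) {
    warning("too few records for EFD+PCA outlier removal; stage skipped")
    return(list(kept = records, removed = list(),
                removals = empty_removals(),
                rounds = data.frame(round = integer(0),
                                    n_before = integer(0),
                                    n_removed = integer(0))))
  }
  records <- lapply(records, ensure_contour)
  kept_idx <- seq_len(n)
  out_idx <- integer(0)
  log <- data.frame(round = integer(0), n_before = integer(0),
                    n_removed = integer(0))
  feats <- t(vapply(records, function(r)
    efd_flatten(efd_coefficients(r$contour, n_harmonics = 10,
                                 normalize_scale = TRUE,
                                 normalize_rotation = FALSE)),
    numeric(40)))
  for (round in seq_len(config$pca_rounds)) {
    f <- feats[kept_idx, , drop = FALSE]
    pc <- stats::prcomp(f, center = TRUE, scale. = FALSE)
    k <- min(config$pca_n_components, ncol(pc$x))
    scores <- pc$x[, seq_len(k), drop = FALSE]
    sds <- apply(scores, 2, stats::sd)
    center <- apply(f, 2, stats::median)
    deviation <- sqrt(rowSums(sweep(f, 2, center)^2))
    bad <- rep(FALSE, length(kept_idx))
    for (j in seq_len(k)) {
      if (sds[j] < 1e-12) next  # zero-variance guard
      bad <- bad | abs(scores[, j]) > config$pca_sd_threshold * sds[j]
    }
    bad <- bad & deviation > config$pca_min_deviation
    log <- rbind(log, data.frame(round = round,
                                 n_before = length(kept_idx),
                                 n_removed = sum(bad)))
    if (!any(bad)) break
    out_idx <- c(out_idx, kept_idx[bad])
    kept_idx <- kept_idx[!bad]
    if (length(kept_idx) < config$pca_n_components + 2) break
  }
  drop <- seq_len(n) %in% out_idx
  res <- split_records(records, drop, "efd_pca",
                       ifelse(drop, "shape_outlier", ""))
  res$rounds <- log
  res
}

#' Recover the mm/px scale from the reference circle
#'
#' The reference circle printed in the imaging rig is much larger than a
#' berry and nearly perfectly round; among removed masks the most
#' circular object (smoothed-outline circularity >= `min_circularity`)
#' is taken and the scale set from its Feret diameter.
#'
#' @param removed_records list of removed `mask_record`s.
#' @param known_diameter_mm physical diameter of the reference circle.
#' @param min_circularity acceptance cut on 4*pi*A/P^2.
#' @return scale in mm/px, or `NA` (with a warning) when no candidate
#'   qualifies.
#' @export
detect_reference_circle <- function(removed_records, known_diameter_mm,
                                    min_circularity = 0.9) {
  stopifnot(known_diameter_mm > 0)
  if (length(removed_records) == 0L) {
    warning("no removed masks: reference circle not found; proceeding in px")
    return(NA_real_)
  }
  removed_records <- lapply(removed_records, ensure_metrics)
  circ <- vapply(removed_records, function(r)
    contour_circularity(r$contour), numeric(1))
  ok <- which(circ >= min_circularity)
  if (length(ok) == 0L) {
    warning("no removed mask with circularity >= ", min_circularity,
            "; proceeding in px")
    return(NA_real_)
  }
  best <- ok[which.max(circ[ok])]
  known_diameter_mm / removed_records[[best]]$metrics$length
}

#' Run the full mask-filtering pipeline on one image
#'
#' Stages in order: merged-mask removal by overlap, geometric filters,
#' EFD + PCA outlier rejection. The report partitions every input mask
#' into exactly one of kept / removed-by-stage.
#'
#' @param records list of `mask_record`s from one image.
#' @param config a [filter_config()].
#' @param image optional (h x w x 3) array for median-color features.
#' @param scale_mm_per_px optional scale applied to berry metrics.
#' @return list of class `filter_result`: `berries` (kept records with
#'   contour, metrics, efd and optional color attached), `report`
#'   (`filter_report`), `removed` (all removed records).
#' @export
run_filter_pipeline <- function(records, config = filter_config(),
                                image = NULL, scale_mm_per_px = NULL) {
  n_input <- length(records)
  s1 <- remove_multiberry_masks(records, config)
  s2 <- geometric_filter(s1$kept, config)
  s3 <- efd_pca_outlier_removal(s2$kept, config)
  berries <- lapply(s3$kept, function(r) {
    r <- ensure_metrics(r)
    if (!is.null(scale_mm_per_px))
      r$metrics <- contour_metrics(r$contour, scale_mm_per_px)
    r$efd <- efd_coefficients(r$contour, n_harmonics = 10,
                              normalize_scale = TRUE,
                              normalize_rotation = FALSE)
    if (!is.null(image)) r$color <- median_color(r$mask, image)
    r
  })
  report <- structure(list(
    n_input = n_input,
    n_removed_overlap = length(s1$removed),
    n_removed_geometric = length(s2$removed),
    n_removed_efd_pca = length(s3$removed),
    n_kept = length(berries),
    removals = rbind(s1$removals, s2$removals, s3$removals),
    pca_rounds = s3$rounds), class = "filter_report")
  stopifnot(report$n_input == report$n_kept + report$n_removed_overlap +
              report$n_removed_geometric + report$n_removed_efd_pca)
  structure(list(berries = berries, report = report,
                 removed = c(s1$removed, s2$removed, s3$removed)),
            class = "filter_result")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("<filter_report> %d masks: %d kept, %d merged (overlap), ",
                     "%d geometric, %d shape outliers\n"),
              x$n_input, x$n_kept, x$n_removed_overlap,
              x$n_removed_geometric, x$n_removed_efd_pca))
  invisible(x)
}

#' Feature table of filtered berries
#'
#' @param berries list of berry records from [run_filter_pipeline()].
#' @return data.frame: identifiers, shape metrics, median color when
#'   available, flattened EFD coefficients.
#' @export
berry_table <- function(berries) {
  if (length(berries) == 0L) return(data.frame())
  rows <- lapply(berries, function(r) {
    m <- r$metrics
    base <- data.frame(id = record_id(r, NA), image_id = r$image_id,
                       cluster_id = r$cluster_id, angle = r$angle,
                       area = m$area, perimeter = m$perimeter,
                       length = m$length, width = m$width,
                       aspect_ratio = m$aspect_ratio,
                       centroid_x = m$centroid[1], centroid_y = m$centroid[2],
                       perimeter_area_ratio = m$perimeter_area_ratio)
    if (!is.null(m$area_mm2)) {
      base$area_mm2 <- m$area_mm2; base$length_mm <- m$length_mm
      base$width_mm <- m$width_mm; base$perimeter_mm <- m$perimeter_mm
    }
    if (!is.null(r$color)) {
      base$median_r <- r$color[["r"]]; base$median_g <- r$color[["g"]]
      base$median_b <- r$color[["b"]]
    }
    cbind(base, as.data.frame(t(efd_flatten(r$efd))))
  })
  do.call(rbind, rows)
}

# --- shared internals -------------------------------------------------

record_id <- function(r, i) if (!is.na(r$id)) r$id else sprintf("m%04d", i)

ensure_contour <- function(r) {
  if (is.null(r$contour)) r$contour <- mask_to_contour(r$mask)
  r
}

ensure_metrics <- function(r) {
  r <- ensure_contour(r)
  if (is.null(r$metrics)) r$metrics <- contour_metrics(r$contour)
  r
}

empty_removals <- function() {
  data.frame(id = character(0), stage = character(0), reason = character(0))
}

split_records <- function(records, drop, stage, reason) {
  ids <- vapply(seq_along(records), function(i)
    record_id(records[[i]], i), character(1))
  list(kept = records[!drop], removed = records[drop],
       removals = data.frame(id = ids[drop],
                             stage = rep(stage, sum(drop)),
                             reason = reason[drop]))
}
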