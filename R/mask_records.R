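# Reading and writing mask records in the automatic-mask-generator JSON
# schema: per object a COCO RLE segmentation, an XYWH bounding box, pixel
# area, predicted IoU and stability score, plus image/cluster/angle tags.

#' Construct a mask record
#'
#' @param mask an `rle_mask` (or binary matrix, encoded on the fly).
#' @param bbox length-4 numeric `(x, y, w, h)`, 0-based, origin top-left.
#'   Recomputed from the mask when `NULL`.
#' @param area foreground pixel count; recomputed when `NULL`.
#' @param predicted_iou,stability_score generator quality scores in [0, 1].
#' @param image_id,cluster_id identifiers.
#' @param angle view angle in degrees (0, 90, 180, 270) or `NA`.
#' @param id record identifier (defaults assigned by [read_mask_records()]).
#' @return An object of class `mask_record`.
#' @export
mask_record <- function(mask, bbox = NULL, area = NULL,
                        predicted_iou = 1, stability_score = 1,
                        image_id = NA_character_, cluster_id = NA_character_,
                        angle = NA_real_, id = NA_character_) {
  if (is.matrix(mask)) mask <- encode_rle(mask)
  stopifnot(inherits(mask, "rle_mask"))
  true_area <- rle_area(mask)
  if (true_area == 0L) stop("mask record must contain foreground pixels")
  true_bbox <- rle_bbox(mask)
  if (is.null(area)) area <- true_area
  if (is.null(bbox)) bbox <- true_bbox
  if (area != true_area) {
    warning(sprintf("stored area %d != decoded pixel count %d; using decoded count",
                    as.integer(area), true_area))
    area <- true_area
  }
  if (!isTRUE(all(bbox == true_bbox))) {
    warning("stored bbox is not the tight box of the mask; recomputed")
    bbox <- true_bbox
  }
  structure(list(mask = mask, bbox = as.numeric(bbox), area = as.integer(area),
                 predicted_iou = predicted_iou,
                 stability_score = stability_score,
                 image_id = image_id, cluster_id = cluster_id,
                 angle = angle, id = id),
            class = "mask_record")
}

# Tight XYWH box of an RLE mask, 0-based.
rle_bbox <- function(rle) {
  m <- decode_rle(rle)
  idx <- which(m == 1L)
  ys <- (idx - 1L) %% nrow(m)
  xs <- (idx - 1L) %/% nrow(m)
  c(min(xs), min(ys), max(xs) - min(xs) + 1L, max(ys) - min(ys) + 1L)
}

#' Read mask records from a generator JSON file
#'
#' @param path JSON file: an array of objects with keys `segmentation`
#'   (`size`, `counts`), `bbox`, `area`, `predicted_iou`,
#'   `stability_score`, and optionally `image_id`, `cluster_id`, `angle`,
#'   `id`. `counts` may be the uncompressed integer dialect or the
#'   compressed string dialect.
#' @param image_id,cluster_id,angle defaults applied to records lacking
#'   their own tags.
#' @return list of `mask_record` objects (possibly empty).
#' @export
read_mask_records <- function(path, image_id = NA_character_,
                              cluster_id = NA_character_, angle = NA_real_) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    r <- raw[[i]]
    for (key in c("segmentation", "bbox", "area", "predicted_iou",
                  "stability_score"))
      if (is.null(r[[key]]))
        stop(sprintf("record %d: missing required key '%s'", i, key))
    seg <- r$segmentation
    if (is.null(seg$size) || is.null(seg$counts))
      stop(sprintf("record %d: missing required key 'segmentation.size/counts'", i))
    counts <- if (is.character(seg$counts[[1]])) seg$counts[[1]] else
      unlist(seg$counts)
    out[[i]] <- mask_record(
      mask = rle_mask(unlist(seg$size), counts),
      bbox = unlist(r$bbox), area = r$area,
      predicted_iou = r$predicted_iou, stability_score = r$stability_score,
      image_id = r$image_id %||% image_id,
      cluster_id = r$cluster_id %||% cluster_id,
      angle = r$angle %||% angle,
      id = r$id %||% sprintf("m%04d", i))
  }
  out
}

#' Write mask records to the generator JSON schema
#' @param records list of `mask_record`s.
#' @param path output JSON path.
#' @export
write_mask_records <- function(records, path) {
  payload <- lapply(records, function(r) {
    list(segmentation = list(size = r$mask$size, counts = r$mask$counts),
         bbox = r$bbox, area = r$area,
         predicted_iou = r$predicted_iou,
         stability_score = r$stability_score,
         image_id = r$image_id, cluster_id = r$cluster_id,
         angle = r$angle, id = r$id)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a region-of-interest sidecar CSV
#' @param path CSV with columns `image_id, x, y, w, h`.
#' @return data.frame keyed by `image_id`.
#' @export
read_roi_sidecar <- function(path) {
  roi <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "x", "y", "w", "h")
  miss <- setdiff(need, names(roi))
  if (length(miss)) stop("ROI sidecar missing columns: ",
                         paste(miss, collapse = ", "))
  roi
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prompt-point grid over a region of interest
#'
#' Points sit at the centers of an n x n uniform partition of the ROI, the
#' geometry an automatic mask generator is prompted with (a 32 x 32 grid
#' over a 2816 x 5472 ROI gives the 88 x 171 px spacing used in practice).
#'
#' @param roi numeric `(x, y, w, h)` in pixels.
#' @param n_per_side points per side (>= 1).
#' @return list with `points` (n^2 x 2 matrix), `n_per_side`, `roi`,
#'   `spacing` (`c(w, h) / n`).
#' @export
generate_point_grid <- function(roi, n_per_side) {
  if (n_per_side < 1) stop("n_per_side must be >= 1")
  if (roi[3] <= 0 || roi[4] <= 0) stop("roi must have positive width and height")
  sx <- roi[3] / n_per_side; sy <- roi[4] / n_per_side
  cx <- roi[1] + (seq_len(n_per_side) - 0.5) * sx
  cy <- roi[2] + (seq_len(n_per_side) - 0.5) * sy
  pts <- as.matrix(expand.grid(x = cx, y = cy))
  list(points = pts, n_per_side = as.integer(n_per_side),
       roi = as.numeric(roi), spacing = c(sx, sy))
}

#' Count isolated objects in a detached-berry validation image
#'
#' Berries detached onto a bright uniform surface are counted by global
#' thresholding at the midpoint of the intensity range followed by
#' 4-connected labeling; components smaller than `min_area` are discarded.
#' The count serves as the ground-truth berry number for a cluster.
#'
#' @param image numeric array (h x w) or (h x w x 3) in [0, 1], or a path
#'   readable by [read_image()].
#' @param min_area minimum component size in pixels.
#' @return integer count.
#' @export
count_isolated_objects <- function(image, min_area = 20) {
  if (is.character(image)) image <- read_image(image)
  gray <- if (length(dim(image)) == 3L) apply(image, c(1, 2), mean) else image
  rng <- range(gray)
  if (diff(rng) < 0.05) return(0L)  # blank canvas
  fg <- (gray < mean(rng)) + 0L     # dark objects on bright surface
  lab <- EBImage::bwlabel(fg)
  if (max(lab) == 0L) return(0L)
  sizes <- tabulate(lab[lab > 0L])
  sum(sizes >= min_area)
}

#' Read an RGB image as an (h x w x channels) array in [0, 1]
#' @param path PNG or JPEG file.
#' @return numeric array, rows = image rows (y), columns = x.
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
}
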