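# Shared fixture builders. Everything is generated in code; no files.

# Independent naive RLE decoder: walks the runs one pixel at a time.
# Deliberately dumb so it cannot share a bug with the vectorised codec.
naive_decode_rle <- function(size, counts) {
  out <- integer(size[1] * size[2])
  pos <- 1L
  val <- 0L
  for (cnt in counts) {
    if (cnt > 0) {
      for (i in seq_len(cnt)) {
        out[pos] <- val
        pos <- pos + 1L
      }
    }
    val <- 1L - val
  }
  matrix(out, nrow = size[1])
}

random_binary_grid <- function(h, w, p = 0.4) {
  matrix(rbinom(h * w, 1L, p), h, w)
}

# Rasterized disk mask; centers live on the half-pixel grid.
disk_mask <- function(cx, cy, r, h, w) {
  m <- matrix(0L, h, w)
  m[outer((1:h) - 0.5 - cy, (1:w) - 0.5 - cx,
          function(a, b) a^2 + b^2) <= r^2] <- 1L
  m
}

# Closed analytic contour sampled from a polar radius function,
# rotated by a random angle, centered at (cx, cy).
polar_contour <- function(rfun, cx = 0, cy = 0, rot = 0, n = 180) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- rfun(th)
  cbind(cx + r * cos(th + rot), cy + r * sin(th + rot))
}

# Mask record rasterized from a polar outline (for EFD+PCA tests).
polar_mask_record <- function(rfun, rot = 0, h = 60, w = 60, id = NULL) {
  poly <- polar_contour(rfun, cx = w / 2, cy = h / 2, rot = rot)
  m <- matrix(0L, h, w)
  grid <- expand.grid(y = 1:h, x = 1:w)
  inside <- bunchpheno:::points_in_polygon(grid$x - 0.5, grid$y - 0.5, poly)
  m[cbind(grid$y[inside], grid$x[inside])] <- 1L
  mask_record(m, id = id %||% sprintf("p%09d", sample.int(1e9, 1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A full synthetic scene with artifacts plus its mask records and truth.
make_scene <- function(seed, n_berries = 45, wing = NULL, angle = 0,
                       artifacts = artifact_config(), ...) {
  cl <- simulate_cluster_3d(cluster_spec(n_berries = n_berries, wing = wing,
                                         seed = seed, ...))
  scene <- render_view(cl, angle)
  scene <- inject_artifacts(scene, artifacts, seed = seed)
  rec <- scene_to_records(scene, image_id = sprintf("img%04d", seed))
  list(cluster = cl, scene = scene, records = rec$records, truth = rec$truth)
}

# Precision/recall of kept berry records against the scene truth.
scene_filter_scores <- function(sc, config = filter_config()) {
  res <- suppressWarnings(suppressMessages(
    run_filter_pipeline(sc$records, config)))
  kept_ids <- vapply(res$berries, function(r) r$id, character(1))
  tp <- sum(sc$truth$kind[sc$truth$id %in% kept_ids] == "berry")
  list(result = res, tp = tp, n_kept = length(kept_ids),
       n_true = sum(sc$truth$kind == "berry"))
}
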