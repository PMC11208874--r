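# Occlusion correction of visible-berry counts (and max berry area):
# linear calibration against ground truth, k-fold cross-validation, and
# angle-to-angle variation statistics.

#' Element-wise maxima across view angles
#'
#' The view with the most visible berries is the least occluded and is
#' the one used to train and apply the count correction.
#'
#' @param series data.frame with columns `cluster_id`, `angle`, and one
#'   or more value columns (e.g. `count`, `max_area`).
#' @param cols value columns to maximise.
#' @return data.frame, one row per cluster, with per-column maxima.
#' @export
max_across_angles <- function(series, cols = c("count", "max_area")) {
  if (nrow(series) == 0L) stop("empty angle series")
  cols <- intersect(cols, names(series))
  if (length(cols) == 0L) stop("no value columns found")
  agg <- stats::aggregate(series[cols],
                          by = list(cluster_id = series$cluster_id),
                          FUN = max, na.rm = TRUE)
  agg
}

#' Fit the linear occlusion-correction model y ~ b0 + b1 x
#'
#' Ordinary least squares of the true metric on the visible metric. With
#' roughly half the berries hidden the slope sits near 2 (1 / visible
#' fraction).
#'
#' @param x visible metric per cluster (count or max area).
#' @param y true metric per cluster.
#' @param target `"count"` or `"max_area"`; controls rounding on
#'   prediction.
#' @return object of class `correction_model`: `beta0`, `beta1`,
#'   `adjusted_r2`, `cv_r2` (NA until [kfold_cv_r2()]), `n`, `target`.
#' @export
fit_linear_correction <- function(x, y, target = c("count", "max_area")) {
  target <- match.arg(target)
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 training pairs")
  if (stats::sd(x) == 0) stop("visible metric is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  n <- length(x)
  structure(list(beta0 = unname(stats::coef(fit)[1]),
                 beta1 = unname(stats::coef(fit)[2]),
                 adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
                 cv_r2 = NA_real_, n = n, target = target),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("<correction_model %s> y = %.3f + %.3f x  (n=%d, adj R2=%.4f%s)\n",
              x$target, x$beta0, x$beta1, x$n, x$adjusted_r2,
              if (is.na(x$cv_r2)) "" else sprintf(", CV R2=%.4f", x$cv_r2)))
  invisible(x)
}

#' k-fold cross-validated R2 of the linear correction
#'
#' Folds come from a seeded shuffle applied after sorting the pairs, so
#' the result is deterministic given the seed and invariant to input row
#' order. Out-of-fold predictions are pooled and a single R2 computed on
#' the pooled residuals.
#'
#' @param x,y training pairs.
#' @param k number of folds (2 <= k <= n).
#' @param seed integer seed.
#' @return pooled cross-validated R2.
#' @export
kfold_cv_r2 <- function(x, y, k = 5, seed = 1) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (k > n) stop("k must not exceed the number of pairs")
  if (k < 2) stop("k must be >= 2")
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- stats::lm(y[!test] ~ x[!test])
    pred[test] <- stats::coef(fit)[1] + stats::coef(fit)[2] * x[test]
  }
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Predict occlusion-corrected metrics
#'
#' Counts are rounded half-up to integers and never corrected below the
#' visible count when the slope is at least 1.
#'
#' @param model a [fit_linear_correction()] model.
#' @param x visible metric values.
#' @return corrected metric values.
#' @export
predict_corrected <- function(model, x) {
  if (!inherits(model, "correction_model")) stop("model is not fitted")
  y <- model$beta0 + model$beta1 * x
  if (model$target == "count") {
    y <- floor(y + 0.5)
    if (model$beta1 >= 1) y <- pmax(y, round(x))
  }
  y
}

#' Angle-to-angle variation statistics
#'
#' Relative change of per-angle counts against the first angle (0
#' degrees), plus opposing- versus adjacent-angle agreement: wings are
#' laterally visible from one axis only, so views 180 degrees apart
#' agree better than views 90 degrees apart.
#'
#' @param series data.frame with `cluster_id`, `angle`, `count` (and
#'   optionally `max_area`).
#' @return list: `per_view` (data.frame with `relative_change` vs the
#'   first angle), `max_abs_relative_change` per cluster,
#'   `opposing_mean_abs_diff`, `adjacent_mean_abs_diff` (mean |count
#'   difference| between opposing and adjacent angle pairs).
#' @export
angle_variation_stats <- function(series) {
  per <- do.call(rbind, lapply(split(series, series$cluster_id), function(s) {
    s <- s[order(s$angle), , drop = FALSE]
    ref <- s$count[1]
    s$relative_change <- if (ref > 0) (s$count - ref) / ref else 0
    s
  }))
  rownames(per) <- NULL
  maxabs <- vapply(split(per, per$cluster_id),
                   function(s) max(abs(s$relative_change)), numeric(1))
  getc <- function(s, a) if (a %in% s$angle) s$count[s$angle == a][1] else NA
  opp <- c(); adj <- c()
  for (s in split(series, series$cluster_id)) {
    c0 <- getc(s, 0); c90 <- getc(s, 90)
    c180 <- getc(s, 180); c270 <- getc(s, 270)
    opp <- c(opp, abs(c0 - c180), abs(c90 - c270))
    adj <- c(adj, abs(c0 - c90), abs(c90 - c180),
             abs(c180 - c270), abs(c270 - c0))
  }
  list(per_view = per, max_abs_relative_change = maxabs,
       opposing_mean_abs_diff = mean(opp, na.rm = TRUE),
       adjacent_mean_abs_diff = mean(adj, na.rm = TRUE))
}
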