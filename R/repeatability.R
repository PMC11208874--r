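# Repeatability (fraction of phenotypic variance attributable to
# genotype) and trait correlations from a genotype x block replicated
# trait table.

#' Aggregate a cluster-level trait table to vine (genotype x block) means
#'
#' Cluster replicates within a vine are averaged; for count-like traits
#' each cluster first contributes its maximum across view angles (the
#' least-occluded view), otherwise the mean across angles is used.
#'
#' @param table data.frame keyed by `genotype`, `block` (and optionally
#'   `vine`, `cluster`, `angle`) with trait columns.
#' @param trait trait column name.
#' @param angle_rule `"mean"` or `"max"` across angles within a cluster.
#' @return data.frame with `genotype`, `block`, `value` (one row per
#'   genotype x block).
#' @export
aggregate_to_vine <- function(table, trait, angle_rule = c("mean", "max")) {
  angle_rule <- match.arg(angle_rule)
  if (!trait %in% names(table))
    stop(sprintf("trait column '%s' not found", trait))
  tb <- table
  if (!"cluster" %in% names(tb)) tb$cluster <- 1L
  if (!"vine" %in% names(tb)) tb$vine <- 1L
  per_cluster <- stats::aggregate(
    tb[[trait]],
    by = list(genotype = tb$genotype, block = tb$block, vine = tb$vine,
              cluster = tb$cluster),
    FUN = if (angle_rule == "max") function(v) max(v, na.rm = TRUE)
          else function(v) mean(v, na.rm = TRUE))
  out <- stats::aggregate(per_cluster$x,
                          by = list(genotype = per_cluster$genotype,
                                    block = per_cluster$block),
                          FUN = mean)
  names(out)[3] <- "value"
  out[order(out$genotype, out$block), , drop = FALSE]
}

#' Repeatability from genotype x block values
#'
#' Additive block effects are removed by centering each block at its
#' block mean, then a one-way genotype ANOVA provides method-of-moments
#' variance components: sigma2_g = max(0, (MS_between - MS_within) / n0)
#' with n0 the standard unbalanced-design replicate coefficient, and
#' repeatability = sigma2_g / (sigma2_g + sigma2_residual), clamped to
#' [0, 1]. This is the fraction of phenotypic variance attributable to
#' genotype and an upper bound on broad-sense heritability.
#'
#' @param values data.frame from [aggregate_to_vine()] (`genotype`,
#'   `block`, `value`), or a numeric vector with `genotype`/`block`
#'   supplied separately.
#' @param genotype,block grouping vectors when `values` is numeric.
#' @return object of class `variance_components`: `sigma2_genotype`,
#'   `sigma2_residual`, `repeatability`, `n_genotypes`,
#'   `mean_replicates`.
#' @export
estimate_repeatability <- function(values, genotype = NULL, block = NULL) {
  if (is.data.frame(values)) {
    genotype <- values$genotype; block <- values$block
    y <- values$value
  } else y <- values
  g <- factor(genotype)
  ok <- !is.na(y)
  y <- y[ok]; g <- droplevels(g[ok])
  if (!is.null(block)) {
    b <- factor(block[ok])
    y <- y - stats::ave(y, b) + mean(y)   # block centering
  }
  ni <- table(g)
  if (nlevels(g) < 2L) stop("need >= 2 genotypes")
  if (all(ni < 2L)) stop("all genotypes are singletons; residual undefined")
  fit <- stats::aov(y ~ g)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msb <- ms[1]; msw <- ms[2]
  N <- length(y); a <- nlevels(g)
  n0 <- (N - sum(ni^2) / N) / (a - 1)
  s2g <- max(0, (msb - msw) / n0)
  rep <- min(1, max(0, s2g / (s2g + msw)))
  structure(list(sigma2_genotype = s2g, sigma2_residual = msw,
                 repeatability = rep, n_genotypes = a,
                 mean_replicates = N / a),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> s2_g=%.4g s2_e=%.4g repeatability=%.3f (%d genotypes, %.1f reps)\n",
              x$sigma2_genotype, x$sigma2_residual, x$repeatability,
              x$n_genotypes, x$mean_replicates))
  invisible(x)
}

#' Pairwise Pearson correlations between traits
#'
#' Correlations are computed on vine-aggregated (genotype x block)
#' values. Constant traits yield `NA` entries.
#'
#' @param table cluster-level trait table (see [aggregate_to_vine()]).
#' @param traits character vector of trait columns.
#' @param angle_rule passed to [aggregate_to_vine()].
#' @return symmetric correlation matrix with unit diagonal.
#' @export
trait_correlations <- function(table, traits, angle_rule = "mean") {
  agg <- lapply(traits, function(tr)
    aggregate_to_vine(table, tr, angle_rule)$value)
  m <- do.call(cbind, agg)
  colnames(m) <- traits
  suppressWarnings(cc <- stats::cor(m, use = "pairwise.complete.obs"))
  sds <- apply(m, 2, stats::sd, na.rm = TRUE)
  cc[sds == 0, ] <- NA; cc[, sds == 0] <- NA
  diag(cc) <- 1
  cc
}

#' Repeatability table for several traits
#'
#' @param table cluster-level trait table.
#' @param traits character vector of trait columns.
#' @param angle_rule per-trait angle rule; `"max"` is applied to traits
#'   named in `count_traits`, `"mean"` otherwise.
#' @param count_traits traits aggregated by max across angles.
#' @return data.frame with one row per trait.
#' @export
repeatability_table <- function(table, traits,
                                count_traits = c("count", "berry_count"),
                                angle_rule = NULL) {
  rows <- lapply(traits, function(tr) {
    rule <- angle_rule %||% if (tr %in% count_traits) "max" else "mean"
    vc <- estimate_repeatability(aggregate_to_vine(table, tr, rule))
    data.frame(trait = tr, sigma2_genotype = vc$sigma2_genotype,
               sigma2_residual = vc$sigma2_residual,
               repeatability = vc$repeatability,
               n_genotypes = vc$n_genotypes,
               mean_replicates = vc$mean_replicates)
  })
  do.call(rbind, rows)
}
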