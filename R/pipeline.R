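# End-to-end orchestration: mask records in, trait tables out, with a
# reproducible run manifest. The heavy lifting lives in the stage
# functions; this file only wires them together and writes files.

#' Run the full phenotyping pipeline
#'
#' Stages: read per-image mask records, filter to berries, build the
#' berry feature table, per-view architecture descriptors, optional
#' occlusion correction against a truth table, optional repeatability
#' from genotype metadata. Outputs are plain CSV/JSON; a rerun with the
#' same config reproduces identical tables.
#'
#' @param config a named list or path to a YAML file with fields:
#'   `records_dir` (directory of mask-record JSON files, one per image),
#'   `out_dir`, and optionally `filter` (overrides for
#'   [filter_config()]), `concavity`, `reference_circle_mm`,
#'   `correction` (`truth_csv`, `target`, `k`, `seed`),
#'   `metadata_csv` (columns cluster_id, genotype, block, vine),
#'   `traits` (architecture trait columns for repeatability).
#' @return invisibly, a list with the main tables and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$records_dir) || !dir.exists(config$records_dir))
    stop("records_dir missing or does not exist: ",
         config$records_dir %||% "<unset>")
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fcfg <- do.call(filter_config, config$filter %||% list())
  concavity <- config$concavity %||% 8

  files <- sort(list.files(config$records_dir, pattern = "\\.json$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no record JSON files in ", config$records_dir)

  berry_rows <- list(); reports <- list(); views <- list()
  scale <- NULL
  for (f in files) {
    records <- read_mask_records(f)
    res <- run_filter_pipeline(records, fcfg)
    if (!is.null(config$reference_circle_mm) && is.null(scale)) {
      s <- suppressWarnings(
        detect_reference_circle(res$removed, config$reference_circle_mm))
      if (!is.na(s)) scale <- s
    }
    if (length(res$berries)) {
      tb <- berry_table(res$berries)
      berry_rows <- c(berry_rows, list(tb))
      v <- res$berries[[1]]
      views[[basename(f)]] <- list(berries = res$berries,
                                   cluster_id = v$cluster_id,
                                   angle = v$angle)
    }
    reports[[basename(f)]] <- unclass(res$report)[
      c("n_input", "n_removed_overlap", "n_removed_geometric",
        "n_removed_efd_pca", "n_kept")]
  }
  berries <- do.call(rbind, berry_rows)
  utils::write.csv(berries, file.path(out_dir, "berries.csv"),
                   row.names = FALSE)
  jsonlite::write_json(reports, file.path(out_dir, "filter_reports.json"),
                       auto_unbox = TRUE, digits = NA)

  arch <- architecture_table(
    Filter(function(v) length(v$berries) >= 3L, views), concavity)
  utils::write.csv(arch, file.path(out_dir, "architecture.csv"),
                   row.names = FALSE)

  counts <- stats::aggregate(
    list(count = berries$id),
    by = list(cluster_id = berries$cluster_id, angle = berries$angle),
    FUN = length)
  counts$max_area <- stats::aggregate(
    berries$area, by = list(berries$cluster_id, berries$angle),
    FUN = max)$x
  utils::write.csv(counts, file.path(out_dir, "counts.csv"),
                   row.names = FALSE)

  correction <- NULL
  ccfg <- config$correction
  if (!is.null(ccfg$truth_csv)) {
    truth <- utils::read.csv(ccfg$truth_csv, stringsAsFactors = FALSE)
    best <- max_across_angles(counts, "count")
    dat <- merge(best, truth, by = "cluster_id")
    model <- fit_linear_correction(dat$count, dat$true_count,
                                   target = ccfg$target %||% "count")
    model$cv_r2 <- kfold_cv_r2(dat$count, dat$true_count,
                               k = ccfg$k %||% 5, seed = ccfg$seed %||% 17)
    correction <- unclass(model)
    jsonlite::write_json(correction, file.path(out_dir, "correction.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  repeat_tab <- NULL
  if (!is.null(config$metadata_csv)) {
    meta <- utils::read.csv(config$metadata_csv, stringsAsFactors = FALSE)
    traits <- config$traits %||% c("compactness", "hull_area", "hull_aspect")
    tab <- merge(arch, meta, by = "cluster_id")
    tab$cluster <- tab$cluster_id
    repeat_tab <- repeatability_table(tab, intersect(traits, names(tab)))
    cnt_tab <- merge(counts, meta, by = "cluster_id")
    cnt_tab$cluster <- cnt_tab$cluster_id
    repeat_tab <- rbind(repeat_tab,
                        repeatability_table(cnt_tab, "count"))
    utils::write.csv(repeat_tab, file.path(out_dir, "repeatability.csv"),
                     row.names = FALSE)
  }

  manifest <- list(config = config, n_images = length(files),
                   n_berries = nrow(berries),
                   scale_mm_per_px = scale,
                   reports = reports,
                   versions = list(package = "bunchpheno",
                                   r = as.character(getRversion())))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(berries = berries, architecture = arch, counts = counts,
                 correction = correction, repeatability = repeat_tab,
                 manifest = manifest))
}

#' Simulate a full imaging experiment to disk
#'
#' Generates a seeded synthetic trial -- clusters with genotype- and
#' block-structured berry numbers, optional wings, rendered at the
#' requested angles with artifacts -- and writes mask-record JSON files,
#' a ground-truth CSV (true berry counts per cluster) and a metadata CSV
#' (genotype/block per cluster) ready for [run_pipeline()].
#'
#' @param out_dir output directory (`records/` subdirectory is created).
#' @param n_genotypes,n_blocks,clusters_per_vine design dimensions.
#' @param angles view angles in degrees.
#' @param seed master seed.
#' @param mean_berries,sigma2_g,sigma2_e berry-count trait model.
#' @param wing_prob probability a cluster carries a wing.
#' @param artifacts an [artifact_config()] applied to every scene.
#' @return invisibly, list of written paths.
#' @export
simulate_experiment <- function(out_dir, n_genotypes = 4, n_blocks = 2,
                                clusters_per_vine = 2,
                                angles = c(0, 90, 180, 270), seed = 1,
                                mean_berries = 45, sigma2_g = 100,
                                sigma2_e = 25, wing_prob = 0.4,
                                artifacts = artifact_config()) {
  rec_dir <- file.path(out_dir, "records")
  dir.create(rec_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- list(); meta <- list()
  withr::with_seed(seed, {
    g_eff <- stats::rnorm(n_genotypes, 0, sqrt(sigma2_g))
    b_eff <- stats::rnorm(n_blocks, 0, sqrt(sigma2_g) / 4)
    cl_seeds <- sample.int(2^30, n_genotypes * n_blocks * clusters_per_vine)
    wings <- stats::runif(length(cl_seeds)) < wing_prob
    wing_az <- stats::runif(length(cl_seeds), 0, 360)
  })
  k <- 0L
  for (gi in seq_len(n_genotypes)) for (bi in seq_len(n_blocks))
    for (ci in seq_len(clusters_per_vine)) {
      k <- k + 1L
      n_b <- max(8, min(130, round(mean_berries + g_eff[gi] + b_eff[bi] +
        withr::with_seed(cl_seeds[k], stats::rnorm(1, 0, sqrt(sigma2_e))))))
      wing <- if (wings[k])
        list(azimuth = wing_az[k], length_frac = 0.45, share = 0.25)
      cl_id <- sprintf("g%02d_b%d_c%d", gi, bi, ci)
      cl <- simulate_cluster_3d(cluster_spec(n_berries = n_b, wing = wing,
                                             seed = cl_seeds[k]))
      for (ang in angles) {
        scene <- render_view(cl, ang)
        scene <- inject_artifacts(scene, artifacts, seed = cl_seeds[k] + ang)
        sr <- scene_to_records(scene,
                               image_id = sprintf("%s_a%03d", cl_id, ang),
                               cluster_id = cl_id)
        write_mask_records(sr$records,
                           file.path(rec_dir,
                                     sprintf("%s_a%03d.json", cl_id, ang)))
      }
      truth[[k]] <- data.frame(cluster_id = cl_id, true_count = n_b,
                               true_max_area = max(pi * cl$radii^2))
      meta[[k]] <- data.frame(cluster_id = cl_id, genotype = gi, block = bi,
                              vine = 1L)
    }
  truth_csv <- file.path(out_dir, "truth.csv")
  meta_csv <- file.path(out_dir, "metadata.csv")
  utils::write.csv(do.call(rbind, truth), truth_csv, row.names = FALSE)
  utils::write.csv(do.call(rbind, meta), meta_csv, row.names = FALSE)
  invisible(list(records_dir = rec_dir, truth_csv = truth_csv,
                 metadata_csv = meta_csv))
}
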