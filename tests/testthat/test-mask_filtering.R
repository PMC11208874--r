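test_that("pairwise overlap matches analytic and brute-force values", {
  sq <- matrix(0L, 20, 20); sq[6:15, 6:15] <- 1L
  half <- matrix(0L, 20, 20); half[6:10, 6:15] <- 1L
  expect_equal(unname(pairwise_overlap(sq, sq)), c(1, 1))
  expect_equal(unname(pairwise_overlap(sq, half)), c(0.5, 1))
  far <- matrix(0L, 20, 20); far[1:2, 1:2] <- 1L
  expect_equal(unname(pairwise_overlap(sq, far)), c(0, 0))
  expect_error(pairwise_overlap(sq, matrix(0L, 20, 20)), "empty")

  set.seed(21)
  for (i in 1:40) {
    a <- random_binary_grid(15, 15, runif(1, 0.2, 0.7))
    b <- random_binary_grid(15, 15, runif(1, 0.2, 0.7))
    if (!any(a == 1) || !any(b == 1)) next
    got <- pairwise_overlap(a, b)
    # pixel-set oracle
    A <- which(a == 1L); B <- which(b == 1L)
    inter <- length(intersect(A, B))
    expect_equal(unname(got["iou"]), inter / length(union(A, B)))
    expect_equal(unname(got["containment"]),
                 inter / min(length(A), length(B)))
    expect_equal(pairwise_overlap(b, a), got)
  }
})

test_that("merged multi-berry masks are removed, children kept", {
  b1 <- disk_mask(12, 15, 6, 40, 40)
  b2 <- disk_mask(24, 15, 6, 40, 40)
  merged <- pmax(b1, b2)
  recs <- list(mask_record(b1, id = "b1"), mask_record(b2, id = "b2"),
               mask_record(merged, id = "uni"))
  res <- remove_multiberry_masks(recs)
  expect_setequal(vapply(res$kept, function(r) r$id, ""), c("b1", "b2"))
  expect_equal(res$removals$id, "uni")
  expect_match(res$removals$reason, "b1")

  # pairwise-disjoint masks are untouched
  res2 <- remove_multiberry_masks(recs[1:2])
  expect_length(res2$removed, 0)

  # exactly one contained child does not trigger removal (min_children = 2)
  res3 <- remove_multiberry_masks(list(mask_record(b1, id = "b1"),
                                       mask_record(pmax(b1, disk_mask(18, 15, 3, 40, 40)),
                                                   id = "parent")))
  expect_length(res3$removed, 0)
})

test_that("geometric filters name the reason for each removal", {
  set.seed(31)
  recs <- lapply(1:40, function(i)
    mask_record(disk_mask(20 + ((i - 1) %% 8) * 22,
                          20 + ((i - 1) %/% 8) * 22,
                          runif(1, 5.5, 6.5), 400, 400),
                id = sprintf("d%02d", i)))
  # reference circle: ~25x the median area
  circle <- mask_record(disk_mask(330, 330, 30, 400, 400), id = "circle")
  # thin rachis segment
  rc <- matrix(0L, 400, 400); rc[80:84, 120:180] <- 1L
  rachis <- mask_record(rc, id = "rachis")
  res <- geometric_filter(c(recs, list(circle, rachis)))
  rem <- res$removals
  expect_equal(rem$reason[rem$id == "circle"], "area")
  expect_equal(rem$reason[rem$id == "rachis"], "aspect")
  expect_false(any(grepl("^d", rem$id)))

  # homogeneous disks only: identity
  res2 <- geometric_filter(recs)
  expect_length(res2$removed, 0)
})

test_that("EFD+PCA removes gross shape outliers and spares the berry bulk", {
  set.seed(22)
  ells <- lapply(1:100, function(i) {
    a <- runif(1, 14, 18); b <- a * runif(1, 0.9, 0.98)
    phi <- runif(1, 0, 2 * pi)
    polar_mask_record(function(th)
      a * b / sqrt((b * cos(th - phi))^2 + (a * sin(th - phi))^2),
      rot = runif(1, 0, 2 * pi))
  })
  stars <- lapply(1:5, function(i)
    polar_mask_record(function(th) 16 * (0.55 + 0.45 * cos(5 * th)),
                      rot = runif(1, 0, 2 * pi), id = sprintf("star%d", i)))
  res <- efd_pca_outlier_removal(c(ells, stars))
  n_star <- sum(grepl("^star", res$removals$id))
  expect_gte(n_star, 4)
  expect_lte(nrow(res$removals) - n_star, 2)
  # kept counts are monotone non-increasing across rounds
  expect_true(all(diff(res$rounds$n_before) <= 0))
})

test_that("EFD+PCA leaves identical shapes untouched and skips tiny scenes", {
  same <- lapply(1:20, function(i) {
    m <- matrix(0L, 30, 30); m[8:22, 8:22] <- 1L
    mask_record(m, id = paste0("s", i))
  })
  res <- efd_pca_outlier_removal(same)
  expect_length(res$removed, 0)

  expect_warning(res2 <- efd_pca_outlier_removal(same[1:5]), "skipped")
  expect_length(res2$removed, 0)
})

test_that("the reference circle is detected among removed masks", {
  circ <- mask_record(disk_mask(120, 120, 100, 260, 260), id = "circle")
  sq <- matrix(0L, 260, 260); sq[30:207, 40:217] <- 1L  # same area as circle
  square <- mask_record(sq, id = "square")
  blobby <- polar_mask_record(function(th) 20 * (1 + 0.3 * sin(3 * th)),
                              id = "blob", h = 260, w = 260)
  scale <- detect_reference_circle(list(square, blobby, circ),
                                   known_diameter_mm = 50)
  expect_equal(scale, 50 / 200, tolerance = 0.02)
  expect_warning(s2 <- detect_reference_circle(list(square, blobby), 50),
                 "circularity")
  expect_true(is.na(s2))
})

test_that("the full filter pipeline recovers berries on synthetic scenes", {
  tp <- 0; kept <- 0; true <- 0
  for (s in 1:6) {
    sc <- make_scene(seed = 400 + s)
    sf <- scene_filter_scores(sc)
    rep <- sf$result$report
    expect_equal(rep$n_input,
                 rep$n_kept + rep$n_removed_overlap +
                   rep$n_removed_geometric + rep$n_removed_efd_pca)
    tp <- tp + sf$tp; kept <- kept + sf$n_kept; true <- true + sf$n_true
  }
  expect_gte(tp / kept, 0.95)
  expect_gte(tp / true, 0.95)
})

test_that("a pure-berry scene passes through the pipeline unchanged", {
  sc <- make_scene(seed = 900, artifacts = artifact_config(
    clamp = FALSE, circle = FALSE, n_stains = 0, n_rachis = 0, n_merged = 0))
  sf <- scene_filter_scores(sc)
  expect_equal(sf$result$report$n_kept, sf$result$report$n_input)
  expect_equal(nrow(sf$result$report$removals), 0)
})

test_that("filtering is deterministic given records and config", {
  sc <- make_scene(seed = 77)
  r1 <- suppressWarnings(suppressMessages(run_filter_pipeline(sc$records)))
  r2 <- suppressWarnings(suppressMessages(run_filter_pipeline(sc$records)))
  expect_identical(berry_table(r1$berries), berry_table(r2$berries))
  expect_identical(r1$report$removals, r2$report$removals)
})
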