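test_that("ECDF profiles are monotone with the right endpoints and quantiles", {
  set.seed(12)
  cent <- cbind(seq(0, 100, length.out = 50), runif(50, 0, 10))
  p <- ecdf_profile(cent, "x")
  expect_true(all(diff(p$cumulative_fraction) >= 0))
  expect_gte(p$cumulative_fraction[1], 0)
  expect_equal(p$cumulative_fraction[100], 1)
  expect_lt(abs(p$quantile_at_25 - 0.25), 0.025)
  expect_lt(abs(p$quantile_at_50 - 0.50), 0.025)
  expect_lt(abs(p$quantile_at_75 - 0.75), 0.025)

  # step cluster: all berries but one at position 0
  n <- 20
  step <- cbind(c(rep(0, n - 1), 100), runif(n))
  ps <- ecdf_profile(step, "x")
  expect_equal(ps$quantile_at_25, (n - 1) / n)

  expect_error(ecdf_profile(cent[1, , drop = FALSE], "x"), "2 berries")
})

test_that("mirroring a cluster point-reflects its profile", {
  set.seed(13)
  for (i in 1:5) {
    n <- sample(20:60, 1)
    cent <- cbind(runif(n, 0, 200), runif(n, 0, 400))
    p <- ecdf_profile(cent, "x")
    pm <- ecdf_profile(cbind(max(cent[, 1]) + min(cent[, 1]) - cent[, 1],
                             cent[, 2]), "x")
    f <- stats::ecdf((cent[, 1] - min(cent[, 1])) * 100 /
                       diff(range(cent[, 1])))
    cc <- p$normalized_coordinates
    expect_true(all(abs(pm$cumulative_fraction - (1 - f(100 - cc)))
                    <= 1 / n + 1e-9))
  }
})

test_that("symmetry classes follow the published quantile thresholds", {
  mk <- function(q25, q50, q75)
    structure(list(quantile_at_25 = q25, quantile_at_50 = q50,
                   quantile_at_75 = q75), class = "ecdf_profile")
  expect_equal(classify_symmetry(mk(0.35, 0.60, 0.85)), "skew_left")
  expect_equal(classify_symmetry(mk(0.15, 0.40, 0.65)), "skew_right")
  expect_equal(classify_symmetry(mk(0.25, 0.50, 0.75)), "symmetric")
  expect_equal(classify_symmetry(mk(0.22, 0.70, 0.75)), "other")
})

test_that("concave hull reaches the convex limit and contains its input", {
  pts <- polar_contour(function(th) rep(30, length(th)), cx = 50, cy = 50,
                       n = 40)
  ch_area <- bunchpheno:::poly_area(pts[grDevices::chull(pts), ])
  for (k in c(4, 8, 40)) {
    h <- concave_hull(pts, concavity = k)
    expect_lt(abs(h$area - ch_area) / ch_area, 0.01)
    expect_true(all(bunchpheno:::points_in_polygon(pts[, 1], pts[, 2],
                                                   h$polygon)))
  }
  expect_error(concave_hull(cbind(1:10, 2 * (1:10)), 5), "collinear")
})

test_that("low hull detail bridges the sinus of a winged cluster", {
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  main <- cbind(60 + 30 * cos(th), 100 + 30 * sin(th))
  wing <- cbind(190 + 30 * cos(th), 100 + 30 * sin(th))
  both <- rbind(main, wing)
  parts <- 2 * bunchpheno:::poly_area(main[grDevices::chull(main), ])
  smooth <- concave_hull(both, concavity = 30)
  detailed <- concave_hull(both, concavity = 4)
  expect_gt(smooth$area, parts)          # the gap is bridged
  expect_gte(smooth$area, detailed$area) # more detail, tighter hull
  expect_true(all(bunchpheno:::points_in_polygon(both[, 1], both[, 2],
                                                 detailed$polygon)))
  expect_lte(smooth$area,
             bunchpheno:::poly_area(both[grDevices::chull(both), ]) + 1e-6)
})

test_that("compactness is the berry-area to hull-area ratio", {
  th <- seq(0, 2 * pi, length.out = 91)[-91]
  disk <- cbind(30 + 10 * cos(th), 30 + 10 * sin(th))
  h <- concave_hull(disk, concavity = 20)
  expect_equal(compactness(bunchpheno:::poly_area(disk), h), 1,
               tolerance = 0.02)
  h4000 <- structure(list(area = 4000), class = "hull_shape")
  expect_equal(compactness(c(pi * 100, pi * 100), h4000), 2 * pi * 100 / 4000)
  expect_error(compactness(10, structure(list(area = 0),
                                         class = "hull_shape")), "zero")
})

test_that("compactness rises monotonically with packing density", {
  comp_at <- function(pd) {
    mean(vapply(1:5, function(s) {
      cl <- simulate_cluster_3d(cluster_spec(n_berries = 40,
                                             packing_density = pd,
                                             seed = 500 + s))
      scene <- render_view(cl, 0)
      ids <- which(scene$visible_px > 0)
      conts <- lapply(ids, function(i) {
        m <- matrix(0L, nrow(scene$owner), ncol(scene$owner))
        m[scene$owner == i] <- 1L
        suppressMessages(mask_to_contour(m))
      })
      hull <- concave_hull(do.call(rbind, conts), concavity = 10)
      compactness(scene$visible_px[ids], hull)
    }, numeric(1)))
  }
  vals <- vapply(c(1.6, 1.25, 1.0), comp_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("shape PCA tracks aspect ratio on an ellipse sweep", {
  asp <- seq(0.3, 0.95, length.out = 50)
  hulls <- lapply(asp, function(a)
    polar_contour(function(th)
      40 * a / sqrt((a * cos(th))^2 + sin(th)^2), n = 120))
  sp <- shape_pca(hulls)
  expect_gte(abs(stats::cor(sp$scores[, 1], asp)), 0.95)
  expect_equal(sum(sp$explained_variance_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(sp$explained_variance_fraction) <= 1e-12))

  same <- lapply(1:5, function(i) hulls[[1]])
  sp2 <- shape_pca(same)
  expect_lt(sum(sp2$scores^2), 1e-12)
  expect_error(shape_pca(hulls[1:2]), "3 hulls")
})
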