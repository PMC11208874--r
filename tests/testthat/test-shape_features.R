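test_that("contour metrics match analytic shapes", {
  rect <- cbind(c(0, 40, 40, 0), c(0, 0, 20, 20))
  m <- contour_metrics(rect)
  expect_equal(m$area, 800)
  expect_equal(m$length, sqrt(40^2 + 20^2), tolerance = 1e-9)
  expect_equal(m$width, 2 * 40 * 20 / sqrt(40^2 + 20^2), tolerance = 1e-9)
  expect_equal(m$aspect_ratio, m$width / m$length)

  circ <- polar_contour(function(th) rep(10, length(th)), n = 360)
  mc <- contour_metrics(circ, scale_mm_per_px = 0.5)
  expect_lt(abs(mc$area - pi * 100) / (pi * 100), 0.01)
  expect_equal(mc$aspect_ratio, 1, tolerance = 0.01)
  expect_equal(mc$area_mm2, mc$area * 0.25)
  expect_equal(mc$length_mm, mc$length * 0.5)

  expect_error(contour_metrics(rect[1:2, ]), "degenerate")
})

test_that("metrics obey scaling laws and traversal invariance", {
  set.seed(5)
  blob <- polar_contour(function(th) 20 + 5 * cos(3 * th) + 2 * sin(2 * th))
  m1 <- contour_metrics(blob)
  for (s in c(0.5, 2, 3.7)) {
    ms <- contour_metrics(blob * s)
    expect_equal(ms$area, m1$area * s^2, tolerance = 1e-9)
    expect_equal(ms$perimeter, m1$perimeter * s, tolerance = 1e-9)
    expect_equal(ms$length, m1$length * s, tolerance = 1e-9)
    expect_equal(ms$aspect_ratio, m1$aspect_ratio, tolerance = 1e-9)
  }
  # starting vertex and direction do not matter
  rolled <- blob[c(50:nrow(blob), 1:49), ]
  reversed <- blob[nrow(blob):1, ]
  for (alt in list(rolled, reversed)) {
    ma <- contour_metrics(alt)
    expect_equal(ma$area, m1$area, tolerance = 1e-9)
    expect_equal(ma$perimeter, m1$perimeter, tolerance = 1e-9)
  }
  # isoperimetric bound
  expect_lte(4 * pi * m1$area / m1$perimeter^2, 1 + 1e-6)
})

test_that("median color summarises mask pixels per channel", {
  img <- array(0, dim = c(10, 10, 3))
  img[, , 1] <- 10 / 255; img[, , 2] <- 20 / 255; img[, , 3] <- 30 / 255
  mask <- matrix(0L, 10, 10); mask[3:6, 3:6] <- 1L
  expect_equal(unname(median_color(mask, img)), c(10, 20, 30))

  # majority tie rule: odd pixel count, upper value wins
  img2 <- array(0, dim = c(5, 5, 3))
  img2[, 4:5, ] <- 100 / 255
  mask2 <- matrix(0L, 5, 5); mask2[1:3, 3] <- 1L; mask2[1:4, 4] <- 1L
  expect_equal(unname(median_color(mask2, img2)), c(100, 100, 100))

  # sort-based oracle on random data
  set.seed(8)
  img3 <- array(runif(300), dim = c(10, 10, 3))
  mask3 <- random_binary_grid(10, 10, 0.5)
  got <- median_color(mask3, img3)
  idx <- which(mask3 == 1L)
  for (ch in 1:3) {
    vals <- sort((img3[, , ch] * 255)[idx])
    n <- length(vals)
    oracle <- if (n %% 2 == 1) vals[(n + 1) / 2] else
      mean(vals[n / 2 + 0:1])
    expect_equal(unname(got[ch]), oracle)
  }
  expect_error(median_color(matrix(0L, 10, 10), img3), "empty")
})

test_that("EFD concentrates ellipse energy in the first harmonic", {
  ell <- polar_contour(function(th)
    20 * 10 / sqrt((10 * cos(th))^2 + (20 * sin(th))^2), n = 240)
  e <- efd_coefficients(ell, 10, normalize_scale = FALSE,
                        normalize_rotation = FALSE)
  expect_gte(efd_harmonic_energy(e)[1], 0.99)
})

test_that("rotation normalization makes coefficients orientation-invariant", {
  ell <- polar_contour(function(th)
    20 * 10 / sqrt((10 * cos(th))^2 + (20 * sin(th))^2), n = 240)
  rot <- function(p, a) p %*% matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  e1 <- efd_coefficients(ell, 8, TRUE, TRUE)
  e2 <- efd_coefficients(rot(ell, 37 * pi / 180) + 11, 8, TRUE, TRUE)
  expect_lt(max(abs(e1$coef - e2$coef)), 1e-6)
})

test_that("reconstruction error is non-increasing in harmonic count", {
  blob <- polar_contour(function(th) 30 + 6 * cos(3 * th) + 3 * sin(5 * th),
                        n = 360)
  # resample the blob uniformly by arc length so reconstruction samples align
  seg <- sqrt(rowSums((blob - rbind(blob[-1, ], blob[1, ]))^2))
  tcum <- c(0, cumsum(seg))
  tgrid <- seq(0, tcum[length(tcum)], length.out = 401)[-401]
  ref <- cbind(stats::approx(tcum, c(blob[, 1], blob[1, 1]), tgrid)$y,
               stats::approx(tcum, c(blob[, 2], blob[1, 2]), tgrid)$y)
  rmse <- vapply(1:20, function(nh) {
    rec <- efd_reconstruct(efd_coefficients(blob, nh, FALSE, FALSE), 400)
    sqrt(mean((rec - ref)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) <= 1e-8))
  # 20-harmonic reconstruction is within 1 px of the source outline
  rec20 <- efd_reconstruct(efd_coefficients(blob, 20, FALSE, FALSE), 400)
  h <- max(vapply(seq_len(400), function(i)
    min(sqrt((blob[, 1] - rec20[i, 1])^2 + (blob[, 2] - rec20[i, 2])^2)),
    numeric(1)))
  expect_lt(h, 1)
})

test_that("reconstruction guards degenerate inputs", {
  circ <- polar_contour(function(th) rep(10, length(th)), cx = 5, cy = -3)
  e <- efd_coefficients(circ, 1, FALSE, FALSE)
  rec <- efd_reconstruct(e, 360)
  d <- sqrt((rec[, 1] - 5)^2 + (rec[, 2] + 3)^2)
  expect_lt(max(abs(d - 10)), 0.01)
  e$coef[] <- 0
  expect_error(efd_reconstruct(e), "zero")
  expect_error(efd_reconstruct(efd_coefficients(circ, 2, FALSE, FALSE), 2),
               "n_points")
})
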