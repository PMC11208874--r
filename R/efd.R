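# Elliptical Fourier descriptors (EFD) of closed outlines.
#
# The outline is parameterised by arc length and each coordinate expanded
# in a truncated Fourier series; harmonic n contributes coefficients
# (a_n, b_n) for x and (c_n, d_n) for y. Translation is always removed.
# Optional normalizations: scale (divide by the first-harmonic semi-major
# axis, or by the harmonic-1 norm when rotation is retained) and rotation
# (rotate shape and starting point onto the first-harmonic ellipse axes).

#' Elliptical Fourier coefficients of a closed contour
#'
#' @param contour n x 2 vertex matrix, implicitly closed.
#' @param n_harmonics number of harmonics (>= 1).
#' @param normalize_scale divide coefficients by the harmonic-1 size so
#'   shapes of different sizes are comparable.
#' @param normalize_rotation rotate shape and starting point onto the
#'   harmonic-1 ellipse axes (orientation-invariant coefficients).
#' @return object of class `efd`: `coef` (n_harmonics x 4 matrix with
#'   columns a, b, c, d), `locus` (removed centroid), `n_harmonics`,
#'   `normalized` flags, `size` (harmonic-1 scale divisor, 1 if not
#'   normalized).
#' @export
efd_coefficients <- function(contour, n_harmonics = 10,
                             normalize_scale = TRUE,
                             normalize_rotation = FALSE) {
  if (!is.matrix(contour) || nrow(contour) < 3L)
    stop("degenerate contour: need at least 3 vertices")
  if (n_harmonics < 1) stop("n_harmonics must be >= 1")
  x <- contour[, 1]; y <- contour[, 2]
  dx <- diff(c(x, x[1])); dy <- diff(c(y, y[1]))
  dt <- sqrt(dx^2 + dy^2)
  keep <- dt > 0
  dx <- dx[keep]; dy <- dy[keep]; dt <- dt[keep]
  if (length(dt) < 3L) stop("degenerate contour: zero total arc length")
  t1 <- cumsum(dt); t0 <- c(0, t1[-length(t1)])
  T <- t1[length(t1)]

  coef <- matrix(0, n_harmonics, 4,
                 dimnames = list(NULL, c("a", "b", "c", "d")))
  for (n in seq_len(n_harmonics)) {
    w <- 2 * pi * n / T
    k <- T / (2 * n^2 * pi^2)
    dcos <- cos(w * t1) - cos(w * t0)
    dsin <- sin(w * t1) - sin(w * t0)
    coef[n, 1] <- k * sum(dx / dt * dcos)
    coef[n, 2] <- k * sum(dx / dt * dsin)
    coef[n, 3] <- k * sum(dy / dt * dcos)
    coef[n, 4] <- k * sum(dy / dt * dsin)
  }
  locus <- poly_centroid(contour)
  size <- 1
  if (normalize_rotation) {
    coef <- efd_normalize_rotation(coef)
    if (normalize_scale) {
      size <- coef[1, 1]
      coef <- coef / size
    }
  } else if (normalize_scale) {
    size <- sqrt(sum(coef[1, ]^2))
    coef <- coef / size
  }
  structure(list(coef = coef, locus = locus,
                 n_harmonics = as.integer(n_harmonics),
                 normalized = c(scale = normalize_scale,
                                rotation = normalize_rotation),
                 size = size),
            class = "efd")
}

# Kuhl-Giardina style normalization: choose the starting-point phase
# aligning the parameter origin with the harmonic-1 major axis, then
# rotate coordinates so that axis lies along +x. Among the four phase
# candidates (theta + k*pi/2) the one maximizing the harmonic-1 semi-axis
# is taken, smallest phase winning ties, which fixes the usual sign
# ambiguities deterministically.
efd_normalize_rotation <- function(coef) {
  a <- coef[1, 1]; b <- coef[1, 2]; c <- coef[1, 3]; d <- coef[1, 4]
  theta0 <- 0.5 * atan2(2 * (a * b + c * d), a^2 + c^2 - b^2 - d^2)
  cands <- sort((theta0 + (0:3) * pi / 2) %% (2 * pi))
  best <- NULL; best_axis <- -Inf
  phase_mat <- function(t) matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
  for (th in cands) {
    h1 <- matrix(coef[1, ], 2, 2, byrow = TRUE) %*% phase_mat(th)
    axis <- h1[1, 1]^2 + h1[2, 1]^2
    if (axis > best_axis + 1e-12) { best_axis <- axis; best <- th }
  }
  th <- best
  n_h <- nrow(coef)
  out <- coef
  for (n in seq_len(n_h))
    out[n, ] <- as.vector(t(matrix(coef[n, ], 2, 2, byrow = TRUE) %*%
                              phase_mat(n * th)))
  psi <- atan2(out[1, 3], out[1, 1])
  spat <- matrix(c(cos(psi), -sin(psi), sin(psi), cos(psi)), 2, 2)
  for (n in seq_len(n_h))
    out[n, ] <- as.vector(t(spat %*% matrix(out[n, ], 2, 2, byrow = TRUE)))
  out
}

#' Reconstruct a contour from elliptical Fourier coefficients
#'
#' Inverse transform of [efd_coefficients()]: samples the truncated
#' Fourier series at `n_points` positions. The removed centroid is
#' restored only when the coefficients are unnormalized.
#'
#' @param efd an `efd` object.
#' @param n_points number of samples (>= 3).
#' @return n_points x 2 contour matrix.
#' @export
efd_reconstruct <- function(efd, n_points = 200) {
  if (n_points < 3) stop("n_points must be >= 3")
  coef <- efd$coef
  if (all(abs(coef) < 1e-15)) stop("all-zero coefficients: degenerate point")
  t <- seq(0, 1, length.out = n_points + 1)[-(n_points + 1)]
  x <- numeric(n_points); y <- numeric(n_points)
  for (n in seq_len(nrow(coef))) {
    cs <- cos(2 * pi * n * t); sn <- sin(2 * pi * n * t)
    x <- x + coef[n, 1] * cs + coef[n, 2] * sn
    y <- y + coef[n, 3] * cs + coef[n, 4] * sn
  }
  if (!any(efd$normalized)) {
    x <- x + efd$locus[1]; y <- y + efd$locus[2]
  }
  cbind(x = x, y = y)
}

#' Fraction of Fourier energy captured by each harmonic
#' @param efd an `efd` object.
#' @return numeric vector summing to 1.
#' @export
efd_harmonic_energy <- function(efd) {
  e <- rowSums(efd$coef^2)
  e / sum(e)
}

#' Flatten an EFD coefficient matrix to a feature vector
#' @param efd an `efd` object.
#' @return named numeric vector a1, b1, c1, d1, a2, ...
#' @export
efd_flatten <- function(efd) {
  v <- as.vector(t(efd$coef))
  names(v) <- paste0(rep(c("a", "b", "c", "d"), efd$n_harmonics),
                     rep(seq_len(efd$n_harmonics), each = 4))
  v
}
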