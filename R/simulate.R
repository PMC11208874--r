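# Ground-truthed synthetic grape clusters: 3D berry packing around a
# vertical rachis, orthographic z-buffer rendering at arbitrary view
# angles, distractor objects and merged masks in the mask-record schema,
# and simulated genotype trials. Every stage of the phenotyping pipeline
# is testable against the generator's ground truth.

#' Specification of a synthetic cluster
#'
#' Defaults emulate a mid-size wine-grape cluster: a few dozen round
#' berries packed around a vertical rachis, conical narrowing toward the
#' tip, and roughly half the berries hidden from any single view.
#'
#' @param n_berries target berry count (5-130 in real clusters).
#' @param berry_radius_mean,berry_radius_sd berry radius in px; radii are
#'   drawn uniformly on mean +/- sd*sqrt(3) (bounded biological
#'   variation).
#' @param rachis_length vertical extent of the berry-bearing rachis, px;
#'   by default scales with the berry count (2.5 px per berry, at least
#'   42 px) so clusters of any size keep a comparable packing and hence
#'   a comparable visible fraction, as real clusters do.
#' @param internode_spacing vertical distance between berry whorls, px.
#' @param axis_radius mean lateral distance of berry centers from the
#'   rachis axis, px.
#' @param taper conical narrowing factor: lateral radius shrinks by this
#'   fraction from peduncle to tip.
#' @param wing optional lateral ramification:
#'   `list(azimuth = deg, length_frac = fraction of rachis_length,
#'   share = fraction of berries on the wing)`.
#' @param packing_density minimum allowed center distance between two
#'   berries as a fraction of the sum of their radii; lower is denser.
#' @param seed integer seed; the cluster is fully deterministic given it.
#' @return list of class `cluster_spec`.
#' @export
cluster_spec <- function(n_berries = 45, berry_radius_mean = 10,
                         berry_radius_sd = 0.8, rachis_length = NULL,
                         internode_spacing = 16, axis_radius = 16,
                         taper = 0.3, wing = NULL,
                         packing_density = 1.0, seed = 1) {
  if (is.null(rachis_length)) {
    ring <- max(2, floor(2 * pi * axis_radius /
                           (packing_density * 2 * berry_radius_mean)))
    rachis_length <- internode_spacing * max(1, ceiling(n_berries / ring))
  }
  stopifnot(n_berries >= 1, berry_radius_mean > 0, berry_radius_sd >= 0,
            rachis_length > 0, internode_spacing > 0, axis_radius >= 0,
            taper >= 0, taper < 1, packing_density > 0)
  if (!is.null(wing))
    stopifnot(wing$share >= 0, wing$share < 1, wing$length_frac > 0)
  structure(list(n_berries = as.integer(n_berries),
                 berry_radius_mean = berry_radius_mean,
                 berry_radius_sd = berry_radius_sd,
                 rachis_length = rachis_length,
                 internode_spacing = internode_spacing,
                 axis_radius = axis_radius, taper = taper, wing = wing,
                 packing_density = packing_density, seed = seed),
            class = "cluster_spec")
}

#' Simulate the 3D berry arrangement of a cluster
#'
#' Berries are placed at internode steps around the vertical rachis with
#' golden-angle azimuths, radial jitter and conical taper; wing berries
#' go on a descending lateral branch at the given azimuth. Overlaps are
#' relaxed until every pairwise center distance reaches
#' `packing_density * (r_i + r_j)`.
#'
#' @param spec a [cluster_spec()].
#' @return list of class `cluster3d`: `centers` (n x 3 matrix, columns
#'   x, y, z with y increasing from peduncle to tip), `radii`,
#'   `is_wing`, `spec`.
#' @export
simulate_cluster_3d <- function(spec) {
  withr::with_seed(spec$seed, {
    n <- spec$n_berries
    n_wing <- if (is.null(spec$wing)) 0L else round(spec$wing$share * n)
    n_main <- n - n_wing
    golden <- pi * (3 - sqrt(5))
    rad <- stats::runif(n, spec$berry_radius_mean - spec$berry_radius_sd * sqrt(3),
                        spec$berry_radius_mean + spec$berry_radius_sd * sqrt(3))

    # berries form a single staggered shell around the rachis: rows of
    # whorls spaced so a row holds as many berries as its ring allows at
    # the packing distance, with conical taper toward the tip
    m_dist <- spec$packing_density * 2 * spec$berry_radius_mean
    xs <- numeric(0); ys <- numeric(0); zs <- numeric(0)
    row <- 0L; placed <- 0L
    while (placed < n_main) {
      h <- row * spec$internode_spacing
      shrink <- 1 - spec$taper * min(1, h / max(spec$rachis_length, 1))
      R <- max(spec$axis_radius * shrink, m_dist / (2 * pi) * 2)
      k <- max(2L, floor(2 * pi * R / m_dist))
      k <- min(k, n_main - placed)
      phase <- row * golden + stats::runif(1, -0.15, 0.15)
      az <- phase + (seq_len(k) - 1L) * 2 * pi / max(k, 1) +
        stats::runif(k, -0.12, 0.12)
      rho <- R * stats::runif(k, 0.92, 1.08)
      xs <- c(xs, rho * cos(az)); zs <- c(zs, rho * sin(az))
      ys <- c(ys, h + stats::runif(k, -0.2, 0.2) * spec$internode_spacing)
      placed <- placed + k
      row <- row + 1L
    }
    centers <- cbind(x = xs, y = ys, z = zs)
    is_wing <- rep(FALSE, n_main)

    if (n_wing > 0L) {
      a <- spec$wing$azimuth * pi / 180
      dir <- c(cos(a), 0.25, sin(a))
      dir <- dir / sqrt(sum(dir^2))
      # the wing is a distinct lateral lobe: its base sits one cluster
      # radius out along the wing azimuth, near the peduncle
      base <- c(1.2 * spec$axis_radius * cos(a), 0.15 * spec$rachis_length,
                1.2 * spec$axis_radius * sin(a))
      wl <- spec$wing$length_frac * spec$rachis_length
      t <- (seq_len(n_wing) - 0.5) / n_wing * wl
      waz <- (seq_len(n_wing) - 1L) * golden
      wrho <- spec$axis_radius * 0.65 * stats::runif(n_wing, 0.5, 1.1)
      # local frame perpendicular to the branch
      u <- c(-dir[3], 0, dir[1]); u <- u / sqrt(sum(u^2))
      v <- c(dir[2] * u[3] - dir[3] * u[2],
             dir[3] * u[1] - dir[1] * u[3],
             dir[1] * u[2] - dir[2] * u[1])
      wing_pts <- t(vapply(seq_len(n_wing), function(i)
        base + t[i] * dir + wrho[i] * (cos(waz[i]) * u + sin(waz[i]) * v),
        numeric(3)))
      colnames(wing_pts) <- c("x", "y", "z")
      centers <- rbind(centers, wing_pts)
      is_wing <- c(is_wing, rep(TRUE, n_wing))
    }

    centers <- relax_packing(centers, rad, spec$packing_density)
    structure(list(centers = centers, radii = rad, is_wing = is_wing,
                   spec = spec), class = "cluster3d")
  })
}

# Iterative pairwise repulsion until all center distances reach
# delta * (r_i + r_j). Errors out when the packing is infeasible.
relax_packing <- function(centers, rad, delta, max_iter = 600, tol = 0.02) {
  n <- nrow(centers)
  if (n < 2L) return(centers)
  mind <- delta * outer(rad, rad, "+")
  diag(mind) <- 0
  for (iter in seq_len(max_iter)) {
    d <- as.matrix(stats::dist(centers))
    viol <- which(d < (1 - tol) * mind & upper.tri(d), arr.ind = TRUE)
    if (nrow(viol) == 0L) return(centers)
    disp <- matrix(0, n, 3)
    for (k in seq_len(nrow(viol))) {
      i <- viol[k, 1]; j <- viol[k, 2]
      dv <- centers[j, ] - centers[i, ]
      dd <- sqrt(sum(dv^2))
      if (dd < 1e-9) { dv <- c(1e-3 * i, 1e-3, -1e-3 * j); dd <- sqrt(sum(dv^2)) }
      push <- 0.5 * (mind[i, j] - dd) / dd
      disp[i, ] <- disp[i, ] - dv * push / 2
      disp[j, ] <- disp[j, ] + dv * push / 2
    }
    centers <- centers + disp
  }
  stop("infeasible packing: relaxation did not converge; lower packing_density or berry count")
}

#' Render a cluster view with z-buffer occlusion
#'
#' The cluster is rotated about the vertical axis, projected
#' orthographically, and each pixel assigned to the nearest berry sphere
#' covering it. Berry detection mimics an automatic mask generator
#' prompted on a coarse point grid: fully visible berries are always
#' segmented, heavily occluded slivers never are, and in between the
#' detection probability ramps linearly with the visible fraction of
#' the berry disk (partially hidden berries are the ones a coarse grid
#' misses). The draw is deterministic given the cluster seed and angle.
#'
#' @param cluster3d a [simulate_cluster_3d()] result.
#' @param angle view angle in degrees, in [0, 360).
#' @param image_size optional `c(height, width)`; the frame is auto-fit
#'   with `margin` when `NULL`, and berries falling outside an explicit
#'   frame raise an error.
#' @param scale mm per px, attached to the scene for physical units.
#' @param margin background border around the cluster for the auto-fit
#'   frame, px.
#' @param detection_ramp `c(lo, hi)`: a berry is never detected below a
#'   visible fraction of `lo`, always detected above `hi`, with a
#'   linearly ramping probability in between.
#' @return object of class `rendered_scene`: `owner` (h x w matrix,
#'   0 = background, i = berry i in front), `centers_px`, `radii`,
#'   `depth`, `true_count`, `true_area_px` (full-disk areas),
#'   `true_area_mm2`, `visible_px`, `visible_frac`, `emitted` (logical),
#'   `visible_count`, `angle`, `scale`, `distractors`, `merged`.
#' @export
render_view <- function(cluster3d, angle, image_size = NULL, scale = 0.5,
                        margin = 120, detection_ramp = c(0.75, 0.95)) {
  stopifnot(angle >= 0, angle < 360)
  th <- angle * pi / 180
  cx <- cluster3d$centers[, 1]; cy <- cluster3d$centers[, 2]
  cz <- cluster3d$centers[, 3]
  xp <- cx * cos(th) + cz * sin(th)
  zp <- -cx * sin(th) + cz * cos(th)
  rad <- cluster3d$radii
  n <- length(rad)

  if (is.null(image_size)) {
    x0 <- floor(min(xp - rad)) - margin
    y0 <- floor(min(cy - rad)) - margin
    w <- ceiling(diff(range(xp)) + 2 * max(rad)) + 2 * margin
    h <- ceiling(diff(range(cy)) + 2 * max(rad)) + 2 * margin
  } else {
    h <- image_size[1]; w <- image_size[2]
    x0 <- floor(min(xp - rad)) - (w - ceiling(diff(range(xp)) + 2 * max(rad))) / 2
    y0 <- floor(min(cy - rad)) - (h - ceiling(diff(range(cy)) + 2 * max(rad))) / 2
  }
  px <- xp - x0; py <- cy - y0
  if (any(px - rad < 0 | px + rad > w | py - rad < 0 | py + rad > h))
    stop("berries fall outside the image frame; enlarge image_size")

  owner <- matrix(0L, h, w)
  depth <- matrix(Inf, h, w)
  ord <- order(zp)  # front first; later spheres rarely win, fewer writes
  for (i in ord) {
    xc <- px[i]; yc <- py[i]; r <- rad[i]
    cols <- max(1L, floor(xc - r) + 1L):min(w, ceiling(xc + r) + 1L)
    rows <- max(1L, floor(yc - r) + 1L):min(h, ceiling(yc + r) + 1L)
    dx <- (cols - 0.5) - xc; dy <- (rows - 0.5) - yc
    d2 <- outer(dy^2, dx^2, "+")
    inside <- d2 <= r^2
    if (!any(inside)) next
    zs <- zp[i] - sqrt(pmax(0, r^2 - d2))
    sub_d <- depth[rows, cols, drop = FALSE]
    win <- inside & (zs < sub_d)
    if (any(win)) {
      sub_o <- owner[rows, cols, drop = FALSE]
      sub_o[win] <- i
      sub_d[win] <- zs[win]
      owner[rows, cols] <- sub_o
      depth[rows, cols] <- sub_d
    }
  }
  vis <- tabulate(owner[owner > 0L], nbins = n)
  full <- pi * rad^2
  frac <- vis / full
  thresh <- withr::with_seed(
    cluster3d$spec$seed + 7919L * (as.integer(angle) + 1L),
    stats::runif(n, detection_ramp[1], detection_ramp[2]))
  emitted <- frac >= thresh
  structure(list(owner = owner, centers_px = cbind(x = px, y = py),
                 radii = rad, depth = zp, true_count = n,
                 true_area_px = full, true_area_mm2 = full * scale^2,
                 visible_px = vis, visible_frac = frac, emitted = emitted,
                 visible_count = sum(emitted), angle = angle,
                 scale = scale, detection_ramp = detection_ramp,
                 is_wing = cluster3d$is_wing,
                 distractors = list(), merged = list()),
            class = "rendered_scene")
}

#' @export
print.rendered_scene <- function(x, ...) {
  cat(sprintf("<rendered_scene %dx%d @%g deg: %d/%d berries visible, %d distractors, %d merged>\n",
              nrow(x$owner), ncol(x$owner), x$angle, x$visible_count,
              x$true_count, length(x$distractors), length(x$merged)))
  invisible(x)
}

#' Configuration of injected non-berry artifacts
#'
#' @param clamp add the holding clamp (elongated rectangle above the
#'   peduncle).
#' @param circle add the size-reference circle, far from the cluster.
#' @param circle_diameter_px reference-circle diameter in px.
#' @param n_stains irregular background stains far from the cluster.
#' @param stain_radius mean stain radius in px.
#' @param n_rachis thin exposed rachis segments.
#' @param n_merged masks covering two touching berries.
#' @return list of class `artifact_config`.
#' @export
artifact_config <- function(clamp = TRUE, circle = TRUE,
                            circle_diameter_px = 100, n_stains = 2,
                            stain_radius = 10, n_rachis = 2, n_merged = 3) {
  structure(list(clamp = clamp, circle = circle,
                 circle_diameter_px = circle_diameter_px,
                 n_stains = n_stains, stain_radius = stain_radius,
                 n_rachis = n_rachis, n_merged = n_merged),
            class = "artifact_config")
}

#' Inject distractor objects and merged masks into a rendered scene
#'
#' Adds the objects an automatic mask generator picks up besides
#' berries: the holding clamp at the peduncle, the reference circle and
#' irregular stains away from the cluster, thin rachis segments, and
#' merged masks covering pairs of touching berries. All additions are
#' labeled in the ground truth.
#'
#' @param scene a [render_view()] scene.
#' @param config an [artifact_config()].
#' @param seed integer seed for stain shapes and merged-pair choice.
#' @return the scene with `distractors` (list of `list(kind, px)`) and
#'   `merged` (list of `list(px, members)`) filled.
#' @export
inject_artifacts <- function(scene, config = artifact_config(), seed = 1) {
  h <- nrow(scene$owner); w <- ncol(scene$owner)
  free <- scene$owner == 0L
  withr::with_seed(seed, {
    dis <- list()
    top_y <- min(scene$centers_px[, 2] - scene$radii)
    axis_x <- stats::median(scene$centers_px[, 1])
    if (config$clamp) {
      y1 <- max(1, round(top_y - 24)); y2 <- max(1, round(top_y - 10))
      x1 <- round(axis_x - 40); x2 <- round(axis_x + 40)
      dis <- c(dis, list(list(kind = "clamp",
                              px = rect_pixels(h, w, x1, x2, y1, y2))))
    }
    if (config$n_rachis > 0) {
      y1 <- max(1, round(top_y - 8)); y2 <- round(top_y + 22)
      dis <- c(dis, list(list(kind = "rachis",
                              px = setdiff(rect_pixels(h, w, round(axis_x - 2),
                                                       round(axis_x + 2), y1, y2),
                                           which(!free)))))
      if (config$n_rachis > 1) {
        xr <- round(max(scene$centers_px[, 1] + scene$radii) + 12)
        ym <- round(stats::median(scene$centers_px[, 2]))
        dis <- c(dis, list(list(kind = "rachis",
                                px = rect_pixels(h, w, xr, xr + 55,
                                                 ym - 2, ym + 2))))
      }
    }
    if (config$circle) {
      r <- config$circle_diameter_px / 2
      cx <- w - r - 6; cy <- r + 6
      dis <- c(dis, list(list(kind = "reference_circle",
                              px = disk_pixels(h, w, cx, cy, r))))
    }
    if (config$n_stains > 0) {
      # stains live in the far corners of the frame, well away from the
      # cluster (the reference circle owns the top-right corner)
      corners <- list(c(12, h - 12), c(12, 12), c(w - 12, h - 12))
      for (s in seq_len(config$n_stains)) {
        ctr <- corners[[(s - 1L) %% length(corners) + 1L]]
        r0 <- config$stain_radius * stats::runif(1, 0.8, 1.3)
        ph <- stats::runif(2, 0, 2 * pi)
        t <- seq(0, 2 * pi, length.out = 72)[-72]
        rr <- r0 * (1 + 0.35 * sin(3 * t + ph[1]) + 0.2 * sin(5 * t + ph[2]))
        poly <- cbind(ctr[1] + pmax(2, rr) * cos(t),
                      ctr[2] + pmax(2, rr) * sin(t))
        dis <- c(dis, list(list(kind = "stain",
                                px = polygon_pixels(h, w, poly))))
      }
    }
    dis <- Filter(function(d) length(d$px) >= 20L, dis)

    merged <- list()
    if (config$n_merged > 0) {
      em <- which(scene$emitted)
      pairs <- touching_pairs(scene, em)
      if (nrow(pairs) > 0L) {
        take <- pairs[sample(nrow(pairs), min(config$n_merged, nrow(pairs))), ,
                      drop = FALSE]
        for (k in seq_len(nrow(take))) {
          ids <- c(take[k, 1], take[k, 2])
          merged <- c(merged, list(list(
            px = which(scene$owner %in% ids), members = ids)))
        }
      }
    }
    scene$distractors <- dis
    scene$merged <- merged
    scene
  })
}

rect_pixels <- function(h, w, x1, x2, y1, y2) {
  cols <- max(1, x1):min(w, x2); rows <- max(1, y1):min(h, y2)
  as.vector(outer(rows, (cols - 1L) * h, "+"))
}

disk_pixels <- function(h, w, cx, cy, r) {
  cols <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
  rows <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
  grid <- expand.grid(y = rows, x = cols)
  keep <- (grid$x - 0.5 - cx)^2 + (grid$y - 0.5 - cy)^2 <= r^2
  grid$y[keep] + (grid$x[keep] - 1L) * h
}

polygon_pixels <- function(h, w, poly) {
  cols <- max(1, floor(min(poly[, 1]))):min(w, ceiling(max(poly[, 1])))
  rows <- max(1, floor(min(poly[, 2]))):min(h, ceiling(max(poly[, 2])))
  grid <- expand.grid(y = rows, x = cols)
  keep <- points_in_polygon(grid$x - 0.5, grid$y - 0.5, poly)
  grid$y[keep] + (grid$x[keep] - 1L) * h
}

# Emitted berry pairs whose visible masks touch (within a 2 px gap).
touching_pairs <- function(scene, ids) {
  out <- matrix(integer(0), 0, 2)
  if (length(ids) < 2L) return(out)
  c_px <- scene$centers_px; rad <- scene$radii
  for (a in seq_along(ids)) {
    for (b in seq_len(a - 1L)) {
      i <- ids[a]; j <- ids[b]
      d <- sqrt(sum((c_px[i, ] - c_px[j, ])^2))
      if (d <= rad[i] + rad[j] + 2) out <- rbind(out, c(i, j))
    }
  }
  out
}

#' Export a rendered scene as mask records
#'
#' The generator doubles as a segmenter stub: emitted berries,
#' distractors and merged masks become records in the exact JSON schema
#' consumed by [read_mask_records()], and the ground-truth labels come
#' along in a companion data.frame.
#'
#' @param scene a scene from [render_view()] (optionally after
#'   [inject_artifacts()]).
#' @param image_id,cluster_id identifiers stamped on the records.
#' @return list: `records` (list of `mask_record`), `truth` (data.frame
#'   with id, kind, berry_id, visible_frac).
#' @export
scene_to_records <- function(scene, image_id = "img1", cluster_id = "c1") {
  h <- nrow(scene$owner); w <- ncol(scene$owner)
  mk <- function(px, id) {
    m <- matrix(0L, h, w); m[px] <- 1L
    mask_record(m, predicted_iou = 0.95, stability_score = 0.97,
                image_id = image_id, cluster_id = cluster_id,
                angle = scene$angle, id = id)
  }
  records <- list(); truth <- list()
  for (i in which(scene$emitted)) {
    id <- sprintf("berry_%03d", i)
    records <- c(records, list(mk(which(scene$owner == i), id)))
    truth <- c(truth, list(data.frame(id = id, kind = "berry", berry_id = i,
                                      visible_frac = scene$visible_frac[i])))
  }
  for (k in seq_along(scene$distractors)) {
    d <- scene$distractors[[k]]
    id <- sprintf("%s_%02d", d$kind, k)
    records <- c(records, list(mk(d$px, id)))
    truth <- c(truth, list(data.frame(id = id, kind = d$kind,
                                      berry_id = NA_integer_,
                                      visible_frac = NA_real_)))
  }
  for (k in seq_along(scene$merged)) {
    m <- scene$merged[[k]]
    id <- sprintf("merged_%02d", k)
    records <- c(records, list(mk(m$px, id)))
    truth <- c(truth, list(data.frame(id = id, kind = "merged",
                                      berry_id = NA_integer_,
                                      visible_frac = NA_real_)))
  }
  list(records = records, truth = do.call(rbind, truth))
}

#' Flat RGB rendering of a scene
#'
#' Berries in dark violet on a bright canvas, distractors in their own
#' flat colors; adequate for color features and visual checks, not
#' photorealism.
#'
#' @param scene a rendered scene.
#' @return (h x w x 3) array in [0, 1].
#' @export
scene_to_image <- function(scene) {
  h <- nrow(scene$owner); w <- ncol(scene$owner)
  img <- array(0.93, dim = c(h, w, 3))
  ch <- h * w
  set_px <- function(img, px, rgb) {
    img[px] <- rgb[1]; img[px + ch] <- rgb[2]; img[px + 2 * ch] <- rgb[3]
    img
  }
  img <- set_px(img, which(scene$owner > 0L), c(0.30, 0.10, 0.35))
  for (d in scene$distractors) {
    col <- switch(d$kind, clamp = c(0.2, 0.2, 0.2),
                  reference_circle = c(0.05, 0.05, 0.05),
                  rachis = c(0.45, 0.35, 0.2), stain = c(0.6, 0.55, 0.5),
                  c(0.5, 0.5, 0.5))
    img <- set_px(img, d$px, col)
  }
  img
}

#' Simulate a replicated genotype trial for one trait
#'
#' value = mu + genotype + block + residual with independent zero-mean
#' normal effects. The residual is drawn per cluster; the truth metadata
#' records both the cluster-level repeatability
#' sigma2_g / (sigma2_g + sigma2_e) and the vine-mean repeatability
#' sigma2_g / (sigma2_g + sigma2_e / clusters_per_vine), which coincide
#' when `clusters_per_vine = 1`.
#'
#' @param n_genotypes,n_blocks,clusters_per_vine design dimensions.
#' @param trait_model `list(mu, sigma2_g, sigma2_block, sigma2_e)`.
#' @param seed integer seed.
#' @return data.frame with `genotype`, `block`, `vine`, `cluster`,
#'   `angle`, `value`; attribute `truth` carries the simulated variance
#'   components and repeatability.
#' @export
simulate_trial <- function(n_genotypes, n_blocks = 3, clusters_per_vine = 5,
                           trait_model = list(mu = 100, sigma2_g = 60,
                                              sigma2_block = 10,
                                              sigma2_e = 40),
                           seed = 1) {
  tm <- trait_model
  stopifnot(tm$sigma2_g >= 0, tm$sigma2_block >= 0, tm$sigma2_e >= 0)
  withr::with_seed(seed, {
    g <- stats::rnorm(n_genotypes, 0, sqrt(tm$sigma2_g))
    b <- stats::rnorm(n_blocks, 0, sqrt(tm$sigma2_block))
    df <- expand.grid(cluster = seq_len(clusters_per_vine),
                      block = seq_len(n_blocks),
                      genotype = seq_len(n_genotypes))
    df$vine <- 1L
    df$angle <- 0
    df$value <- tm$mu + g[df$genotype] + b[df$block] +
      stats::rnorm(nrow(df), 0, sqrt(tm$sigma2_e))
    df <- df[c("genotype", "block", "vine", "cluster", "angle", "value")]
    attr(df, "truth") <- list(
      sigma2_g = tm$sigma2_g, sigma2_e = tm$sigma2_e,
      repeatability_cluster = if (tm$sigma2_g + tm$sigma2_e > 0)
        tm$sigma2_g / (tm$sigma2_g + tm$sigma2_e) else 0,
      repeatability_vine_mean = if (tm$sigma2_g + tm$sigma2_e > 0)
        tm$sigma2_g / (tm$sigma2_g + tm$sigma2_e / clusters_per_vine) else 0)
    df
  })
}
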