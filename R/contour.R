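# Pixel-edge contour tracing.
#
# Contours are traced on the boundaries BETWEEN pixels, not through pixel
# centers: pixel (x, y) covers the unit square [x, x+1] x [y, y+1]. This
# makes the shoelace area of the traced outer boundary exactly equal to
# the pixel count of a hole-free connected component, which anchors all
# downstream area bookkeeping.

#' Extract the outer contour of the largest connected component
#'
#' Connectivity is 4-connected. When a mask has several components the
#' largest is traced and the rest are reported via a message; berry masks
#' are expected to be single blobs.
#'
#' @param mask binary matrix (height x width), an `rle_mask`, or a
#'   `mask_record`.
#' @return n x 2 numeric matrix of (x, y) vertices in 0-based pixel-corner
#'   coordinates, implicitly closed, collinear runs merged. The vertex
#'   orientation gives a positive shoelace area.
#' @export
mask_to_contour <- function(mask) {
  m <- as_binary_matrix(mask)
  if (!any(m == 1L)) stop("empty mask: no foreground pixels")
  lab <- EBImage::bwlabel(m)
  if (max(lab) > 1L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which.max(sizes)
    message(sprintf("mask has %d components; tracing the largest (%d px), dropping %d px",
                    max(lab), sizes[keep], sum(sizes) - sizes[keep]))
    m <- (lab == keep) + 0L
  }
  trace_pixel_boundary(m)
}

as_binary_matrix <- function(mask) {
  if (inherits(mask, "mask_record")) mask <- mask$mask
  if (inherits(mask, "rle_mask")) mask <- decode_rle(mask)
  if (is.logical(mask)) mask <- mask + 0L
  storage.mode(mask) <- "integer"
  mask
}

# Trace boundary loops of a single 4-connected component and return the
# outer loop (largest positive signed area). Directed boundary edges are
# emitted per pixel side facing background; shared sides cancel. At
# checkerboard corners the out-edge turning toward the interior is
# preferred so each loop stays around its own pocket.
trace_pixel_boundary <- function(m) {
  h <- nrow(m); w <- ncol(m)
  fg <- which(m == 1L)
  ys <- (fg - 1L) %% h          # 0-based pixel y
  xs <- (fg - 1L) %/% h         # 0-based pixel x

  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  up    <- pad[cbind(ys + 1L, xs + 2L)] == 0L
  down  <- pad[cbind(ys + 3L, xs + 2L)] == 0L
  left  <- pad[cbind(ys + 2L, xs + 1L)] == 0L
  right <- pad[cbind(ys + 2L, xs + 3L)] == 0L

  # vertex id: corner (x, y) -> x * (h + 1) + y; directions 1:+x 2:+y 3:-x 4:-y
  vid <- function(x, y) x * (h + 1L) + y
  e_from <- c(vid(xs[up],        ys[up]),          # top: (x,y)->(x+1,y)
              vid(xs[right] + 1L, ys[right]),      # right: ->(x+1,y+1)
              vid(xs[down] + 1L,  ys[down] + 1L),  # bottom: ->(x,y+1)
              vid(xs[left],       ys[left] + 1L))  # left: ->(x,y)
  e_to   <- c(vid(xs[up] + 1L,    ys[up]),
              vid(xs[right] + 1L, ys[right] + 1L),
              vid(xs[down],       ys[down] + 1L),
              vid(xs[left],       ys[left]))
  e_dir  <- rep(1:4, c(sum(up), sum(right), sum(down), sum(left)))

  n_e <- length(e_from)
  ord <- order(e_from)
  from_sorted <- e_from[ord]
  first_idx <- which(!duplicated(from_sorted))
  starts <- from_sorted[first_idx]          # unique start vertices
  used <- logical(n_e)

  out_edges <- function(v) {
    pos <- findInterval(v, starts)
    if (pos == 0L || starts[pos] != v) return(integer(0))
    i <- first_idx[pos]
    j <- i
    while (j < n_e && from_sorted[j + 1L] == v) j <- j + 1L
    ord[i:j]
  }
  right_turn <- c(2L, 3L, 4L, 1L)  # +x -> +y -> -x -> -y (interior side)

  loops <- list(); areas <- numeric(0)
  for (e0 in seq_len(n_e)) {
    if (used[e0]) next
    path <- integer(256); np <- 0L
    e <- e0
    repeat {
      used[e] <- TRUE
      np <- np + 1L
      if (np > length(path)) path <- c(path, integer(length(path)))
      path[np] <- e_from[e]
      cand <- out_edges(e_to[e])
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break
      if (length(cand) == 1L) e <- cand[1L]
      else {
        pref <- c(right_turn[e_dir[e]], e_dir[e],
                  right_turn[right_turn[e_dir[e]]])
        e <- cand[order(match(e_dir[cand], pref))][1L]
      }
    }
    v <- path[seq_len(np)]
    poly <- cbind(x = v %/% (h + 1L), y = v %% (h + 1L))
    loops[[length(loops) + 1L]] <- poly
    areas <- c(areas, poly_signed_area(poly))
  }
  poly <- loops[[which.max(areas)]]
  merge_collinear(poly)
}

merge_collinear <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(poly)
  prev <- rbind(poly[n, ], poly[-n, ])
  nxt <- rbind(poly[-1, ], poly[1, ])
  cross <- (poly[, 1] - prev[, 1]) * (nxt[, 2] - poly[, 2]) -
           (poly[, 2] - prev[, 2]) * (nxt[, 1] - poly[, 1])
  keep <- abs(cross) > 1e-12
  if (!any(keep)) keep[1] <- TRUE
  poly[keep, , drop = FALSE]
}
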