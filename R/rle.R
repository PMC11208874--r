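# COCO run-length encoding of binary masks.
#
# Dialect: uncompressed COCO RLE. Runs alternate background/foreground,
# the first run counts background pixels (and may be 0), and pixels are
# scanned in column-major order over the (height x width) grid -- which is
# exactly R's native matrix layout, so decode/encode are vectorised.

#' Construct a run-length-encoded mask
#'
#' @param size integer vector `c(height, width)` in pixels.
#' @param counts integer vector of run lengths, background first,
#'   alternating background/foreground; or a COCO compressed-string
#'   encoding (see [rle_from_string()]), which is canonicalized.
#' @return An object of class `rle_mask` with fields `size` and `counts`.
#' @export
rle_mask <- function(size, counts) {
  size <- as.integer(size)
  if (length(size) != 2L || any(is.na(size)) || any(size < 1L))
    stop("`size` must be two positive integers (height, width)")
  if (is.character(counts)) counts <- rle_from_string(counts)
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0))
    stop("malformed RLE: run lengths must be non-negative")
  if (sum(counts) != prod(size))
    stop(sprintf("malformed RLE: run lengths sum to %d, expected %d pixels",
                 sum(counts), prod(size)))
  structure(list(size = size, counts = as.integer(counts)),
            class = "rle_mask")
}

#' @export
print.rle_mask <- function(x, ...) {
  cat(sprintf("<rle_mask %d x %d, %d runs, %d foreground px>\n",
              x$size[1], x$size[2], length(x$counts), rle_area(x)))
  invisible(x)
}

#' Number of foreground pixels encoded by an RLE mask
#' @param rle an `rle_mask`.
#' @return integer pixel count.
#' @export
rle_area <- function(rle) {
  cnt <- rle$counts
  fg <- seq_along(cnt) %% 2L == 0L  # even positions are foreground runs
  sum(cnt[fg])
}

#' Decode a COCO RLE mask to a binary pixel grid
#'
#' @param rle an `rle_mask` (or a list with `size` and `counts`).
#' @return Integer matrix of dimension (height, width) with entries 0/1;
#'   pixel (x, y) in 0-based image coordinates is element `[y + 1, x + 1]`.
#' @export
decode_rle <- function(rle) {
  if (!inherits(rle, "rle_mask")) rle <- rle_mask(rle$size, rle$counts)
  vals <- rep_len(c(0L, 1L), length(rle$counts))
  matrix(rep(vals, rle$counts), nrow = rle$size[1])
}

#' Encode a binary pixel grid as a COCO RLE mask
#'
#' Round-trip identity with [decode_rle()] holds for every binary grid.
#'
#' @param grid matrix with entries 0/1 (or logical).
#' @return An `rle_mask`.
#' @export
encode_rle <- function(grid) {
  if (is.logical(grid)) grid <- grid + 0L
  v <- as.integer(grid)
  if (any(is.na(v)) || !all(v %in% c(0L, 1L)))
    stop("`grid` must be binary (0/1 or logical)")
  r <- rle(v)
  counts <- r$lengths
  if (length(v) && r$values[1] == 1L) counts <- c(0L, counts)
  rle_mask(dim(grid), counts)
}

#' Decode a COCO compressed RLE string to run lengths
#'
#' The compressed dialect stores each run length in 5-bit chunks offset
#' by 48, with a continuation bit, and runs after the second as the
#' difference from the run two positions earlier.
#'
#' @param s character scalar.
#' @return integer vector of run lengths.
#' @export
rle_from_string <- function(s) {
  bytes <- utf8ToInt(s) - 48L
  counts <- integer(0)
  i <- 1L
  while (i <= length(bytes)) {
    x <- 0; k <- 0L; more <- TRUE
    while (more) {
      c6 <- bytes[i]; i <- i + 1L
      val <- c6 %% 32L
      x <- x + val * 2^(5L * k)
      more <- c6 >= 32L
      k <- k + 1L
      if (!more && val >= 16L) x <- x - 2^(5L * k)  # sign-extend last chunk
    }
    m <- length(counts)
    if (m >= 2L) x <- x + counts[m - 1L]
    counts <- c(counts, x)
  }
  as.integer(counts)
}

#' Encode run lengths as a COCO compressed RLE string
#' @param counts integer vector of run lengths.
#' @return character scalar.
#' @export
rle_to_string <- function(counts) {
  out <- integer(0)
  for (j in seq_along(counts)) {
    x <- counts[j]
    if (j > 2L) x <- x - counts[j - 2L]
    repeat {
      c5 <- x %% 32L
      x <- (x - c5) %/% 32L
      if (x != 0 && x != -1) {
        more <- TRUE
      } else {
        # finished unless the sign bit of this chunk disagrees with x
        sign_bit <- c5 >= 16L
        more <- (x == -1 && !sign_bit) || (x == 0 && sign_bit)
      }
      if (more) c5 <- c5 + 32L
      out <- c(out, c5 + 48L)
      if (!more) break
    }
  }
  intToUtf8(out)
}
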