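# Independent brute-force oracles and small fixture builders used across
# the suite.  These deliberately avoid the package's vectorized code paths.

# Naive O(H*W*window) re-implementation of the column-local threshold:
# for each pixel, the window is the `w` nearest rows in its column
# (half above, half below, shifted inward at the edges), excluding the
# pixel itself; bright iff strictly greater than the window mean.
oracle_binarize <- function(gray, w) {
  h <- nrow(gray)
  half <- w %/% 2
  out <- matrix(FALSE, h, ncol(gray))
  for (j in seq_len(ncol(gray))) {
    for (r in seq_len(h)) {
      lo <- max(1, min(r - half, h - w))
      nbr <- setdiff(lo:(lo + w), r)
      out[r, j] <- gray[r, j] > mean(gray[nbr, j])
    }
  }
  out
}

# Per-pixel run counter for one logical column.
oracle_rle <- function(column) {
  bright <- logical(0)
  lengths <- integer(0)
  for (p in column) {
    n <- length(bright)
    if (n > 0L && bright[n] == p) {
      lengths[n] <- lengths[n] + 1L
    } else {
      bright <- c(bright, p)
      lengths <- c(lengths, 1L)
    }
  }
  list(bright = bright, lengths = lengths)
}

# Exhaustive sign-test oracle: enumerate all 2^n sign patterns and count
# those at least as lopsided as min-count k.
oracle_sign_p <- function(n, k) {
  pats <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), n)))
  mins <- apply(pats, 1L, function(s) min(sum(s > 0), sum(s < 0)))
  mean(mins <= k)
}

# Recovered per-band thickness (px) in the fixture's top-to-bottom order.
recovered_px <- function(fx, m) {
  tr <- fx$truth
  rec <- numeric(length(tr$thickness_px))
  rec[tr$band_bright] <- m$avg_bright_um / m$pixel_length_um
  rec[!tr$band_bright] <- m$avg_dark_um / m$pixel_length_um
  rec
}

# Plain gray RGB canvas for hand-built annotation tests.
gray_canvas <- function(h, w, level = 120) {
  array(level, dim = c(h, w, 3L))
}

set_px <- function(img, row, col, rgb) {
  img[row, col, ] <- rep(rgb, each = length(row) * length(col))
  img
}

# Axis-aligned yellow rectangle: horizontal lines at rows r1/r2 spanning
# cols c1..c2, vertical lines at cols c1/c2 spanning rows r1..r2.
draw_rect <- function(img, r1, r2, c1, c2, rgb = c(255, 255, 0)) {
  img <- set_px(img, r1, c1:c2, rgb)
  img <- set_px(img, r2, c1:c2, rgb)
  img <- set_px(img, r1:r2, c1, rgb)
  set_px(img, r1:r2, c2, rgb)
}

# Binary column-runs matrix from a list of per-column run specs
# (list(bright = ..., lengths = ...)).
binary_from_runs <- function(specs) {
  cols <- lapply(specs, function(s) rep(s$bright, s$lengths))
  h <- unique(vapply(cols, length, integer(1)))
  stopifnot(length(h) == 1L)
  matrix(unlist(cols), h, length(cols))
}
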