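# Stage 2: grayscale, contrast stretch, column-local threshold, repair.

#' Convert a cropped RGB image to grayscale
#'
#' Standard luma transform: `round(0.2989 R + 0.5870 G + 0.1140 B)`,
#' half-up rounding, clamped to 0..255.
#'
#' @param image H x W x 3 RGB array (0..255).
#' @return H x W numeric matrix of intensities in 0..255.
#' @export
to_grayscale <- function(image) {
  .assert_rgb(image)
  g <- 0.2989 * image[, , 1] + 0.5870 * image[, , 2] + 0.1140 * image[, , 3]
  .clamp(.round_half_up(g), 0, 255)
}

#' Percentile contrast stretch
#'
#' Linearly rescales intensities so that `saturation_fraction` of the pixel
#' mass is saturated at each end (default 1%): with `lo` and `hi` the
#' corresponding quantiles, output is `round(255 (x - lo) / (hi - lo))`
#' clamped to 0..255.  A constant image (hi == lo) is returned unchanged.
#'
#' @param gray Numeric intensity matrix (0..255).
#' @param params A [threshold_params()] object.
#' @return Stretched intensity matrix of the same dimensions.
#' @export
stretch_contrast <- function(gray, params = threshold_params()) {
  s <- params$saturation_fraction
  q <- stats::quantile(as.vector(gray), probs = c(s, 1 - s), names = FALSE, type = 7)
  lo <- q[1]
  hi <- q[2]
  if (hi == lo) return(gray)
  .clamp(.round_half_up(255 * (gray - lo) / (hi - lo)), 0, 255)
}

#' Column-local adaptive binarization
#'
#' Classifies each pixel bright or dark against the mean intensity of the
#' `window_size` pixels nearest to it in its own column, excluding the pixel
#' itself (half above, half below; at the top and bottom edges the window is
#' shifted inward so exactly `window_size` pixels are always used).  A pixel
#' is bright iff its intensity is strictly greater than that mean; equality
#' maps to dark.
#'
#' @param gray Numeric intensity matrix; must have more rows than
#'   `window_size`.
#' @param params A [threshold_params()] object.
#' @return Logical matrix, `TRUE` = bright lamella.
#' @export
binarize_columns <- function(gray, params = threshold_params()) {
  w <- params$window_size
  h <- nrow(gray)
  if (h <= w) {
    .lamella_stop("image_too_short_error",
                  sprintf("image height (%d) must exceed the window size (%d)", h, w))
  }
  half <- w %/% 2L
  cs <- apply(gray, 2L, cumsum)                      # h x W column cumsums
  cs0 <- rbind(0, cs)                                # prepend zero row
  r <- seq_len(h)
  lo <- pmax(1L, pmin(r - half, h - w))              # window rows lo..lo+w (incl. center)
  hi <- lo + w
  win_sum <- cs0[hi + 1L, , drop = FALSE] - cs0[lo, , drop = FALSE] - gray
  gray > win_sum / w
}

#' Repair floating pixels
#'
#' Scans each column top to bottom and recolors isolated wrong-color runs:
#' a maximal run of `max_floating_run` or fewer pixels lying strictly
#' between two runs of the opposite color is flipped to match its
#' surroundings (merging it with its neighbors), and the scan continues on
#' the updated column.  Runs touching the top or bottom edge are never
#' flipped, since they are not inside a lamella.
#'
#' @param binary Logical matrix from [binarize_columns()].
#' @param params A [threshold_params()] object.
#' @return Repaired logical matrix.
#' @export
fix_floating_pixels <- function(binary, params = threshold_params()) {
  k <- params$max_floating_run
  if (k == 0L) return(binary)
  out <- binary
  for (j in seq_len(ncol(binary))) {
    r <- rle(binary[, j])
    if (length(r$lengths) >= 3L) {
      out[, j] <- inverse.rle(.repair_runs(r, k))
    }
  }
  out
}

# Single top-to-bottom pass over a column's run-length encoding: flip
# interior runs of length <= k (their neighbors are necessarily the
# opposite color), merging with both neighbors, then continue the scan
# past the merged run.
.repair_runs <- function(r, k) {
  len <- r$lengths
  val <- r$values
  i <- 2L
  while (i <= length(len) - 1L) {
    if (len[i] <= k) {
      len[i - 1L] <- len[i - 1L] + len[i] + len[i + 1L]
      len <- len[-c(i, i + 1L)]
      val <- val[-c(i, i + 1L)]
      # merged run keeps the surrounding color; next unexamined run is now at i
    } else {
      i <- i + 1L
    }
  }
  list(lengths = len, values = val)
}
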