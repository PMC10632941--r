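# Internal helpers shared across the pipeline stages.

# Classed conditions so callers can distinguish failure modes programmatically.
.lamella_stop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "lamellaR_error")))
}

# Conventional half-up rounding; base round() is round-half-even, which would
# make 8-bit intensity conversions depend on parity.
.round_half_up <- function(x) floor(x + 0.5)

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# TRUE for an H x W x 3 numeric raster with values in [0, 255].
.is_rgb_array <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L && is.numeric(x)
}

.assert_rgb <- function(x, what = "image") {
  if (!.is_rgb_array(x)) {
    .lamella_stop("invalid_image_error",
                  sprintf("%s must be an H x W x 3 numeric array of 8-bit RGB values", what))
  }
  if (dim(x)[1] < 2L || dim(x)[2] < 2L) {
    .lamella_stop("invalid_image_error",
                  sprintf("%s must be at least 2 x 2 pixels", what))
  }
  invisible(x)
}

# Logical mask of pixels matching an RGB triple within +/- tolerance per channel.
.color_mask <- function(image, rgb, tolerance = 0) {
  abs(image[, , 1] - rgb[1]) <= tolerance &
    abs(image[, , 2] - rgb[2]) <= tolerance &
    abs(image[, , 3] - rgb[3]) <= tolerance
}

.validate_expected_counts <- function(n_bright, n_dark) {
  if (length(n_bright) != 1L || length(n_dark) != 1L ||
      is.na(n_bright) || is.na(n_dark) ||
      n_bright < 1 || n_dark < 1 ||
      n_bright != as.integer(n_bright) || n_dark != as.integer(n_dark)) {
    .lamella_stop("invalid_counts_error",
                  "expected lamella counts must be integers >= 1")
  }
  if (abs(n_bright - n_dark) > 1) {
    .lamella_stop("invalid_counts_error",
                  "bright and dark lamellae alternate, so expected counts may differ by at most 1")
  }
  invisible(c(n_bright = as.integer(n_bright), n_dark = as.integer(n_dark)))
}
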