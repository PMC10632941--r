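#' Fiducial marker color conventions
#'
#' The annotation protocol marks the measurement rectangle in pure yellow,
#' its two top corners with red pixels and its two bottom corners with green
#' pixels, using fixed RGB codes placed with a pixel editor.  Matching is
#' exact by default; `tolerance` admits +/- k per channel for images that
#' passed through a lossy encoder (lossless TIFF/PNG inputs are assumed).
#'
#' @param red,green,yellow RGB triples (0-255) identifying the top-corner,
#'   bottom-corner and rectangle colors.
#' @param tolerance Per-channel absolute tolerance for marker matching;
#'   default 0 (exact match).
#' @return An object of class `marker_colors`.
#' @examples
#' marker_colors()
#' @export
marker_colors <- function(red = c(237, 28, 36),
                          green = c(34, 177, 76),
                          yellow = c(255, 255, 0),
                          tolerance = 0) {
  for (nm in c("red", "green", "yellow")) {
    v <- get(nm)
    if (length(v) != 3L || any(v < 0) || any(v > 255)) {
      .lamella_stop("invalid_config_error",
                    sprintf("'%s' must be an RGB triple in 0..255", nm))
    }
  }
  if (identical(red, green) || identical(red, yellow) || identical(green, yellow)) {
    .lamella_stop("invalid_config_error", "marker colors must be pairwise distinct")
  }
  if (tolerance < 0) {
    .lamella_stop("invalid_config_error", "'tolerance' must be >= 0")
  }
  structure(list(red = as.numeric(red), green = as.numeric(green),
                 yellow = as.numeric(yellow), tolerance = as.numeric(tolerance)),
            class = "marker_colors")
}

#' Binarization parameters
#'
#' Tunables of the measurement-image stage.  `window_size` is the number of
#' neighboring pixels in the same column whose mean intensity each pixel is
#' compared against (the pixel itself is excluded; the window is split
#' half-above/half-below and shifted inward at the image edges so exactly
#' `window_size` pixels are always used).  `saturation_fraction` is the tail
#' mass clipped at each end in the contrast stretch.  `max_floating_run` is
#' the largest isolated wrong-color run, fully inside a lamella, that the
#' repair pass recolors.
#'
#' `window_size` should exceed the thickest *bright* lamella in pixels: a
#' bright pixel whose entire window is equally bright has intensity equal to
#' the window mean and is classed dark by the strict-inequality rule.  The
#' default of 20 suits lamellae up to ~6 um at the default 0.3185 um/px
#' calibration.
#'
#' @param window_size Even integer >= 2; default 20.
#' @param saturation_fraction Fraction in [0, 0.5); default 0.01.
#' @param max_floating_run Integer >= 0; default 2.
#' @return An object of class `threshold_params`.
#' @examples
#' threshold_params()
#' threshold_params(window_size = 32)
#' @export
threshold_params <- function(window_size = 20L,
                             saturation_fraction = 0.01,
                             max_floating_run = 2L) {
  if (length(window_size) != 1L || window_size < 2 || window_size %% 2 != 0) {
    .lamella_stop("invalid_config_error", "'window_size' must be an even integer >= 2")
  }
  if (saturation_fraction < 0 || saturation_fraction >= 0.5) {
    .lamella_stop("invalid_config_error", "'saturation_fraction' must be in [0, 0.5)")
  }
  if (max_floating_run < 0) {
    .lamella_stop("invalid_config_error", "'max_floating_run' must be >= 0")
  }
  structure(list(window_size = as.integer(window_size),
                 saturation_fraction = as.numeric(saturation_fraction),
                 max_floating_run = as.integer(max_floating_run)),
            class = "threshold_params")
}
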