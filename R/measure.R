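# Stage 3: run-length encoding, column quality filtering, averaging.

#' Run-length encode every column
#'
#' Decomposes each column of the binary measurement image into its maximal
#' runs of consecutive same-color pixels, top to bottom.  Each color change
#' marks the start of a new lamella; the run lengths are the per-column
#' lamellar thicknesses in pixels.
#'
#' @param binary Logical matrix, `TRUE` = bright.
#' @return An object of class `column_runs`: a list with one element per
#'   column, each holding `bright` (logical run colors) and `lengths`
#'   (integer run lengths), plus attributes `height` and `n_columns`.
#' @export
run_length_encode <- function(binary) {
  if (!is.matrix(binary) || !is.logical(binary)) {
    .lamella_stop("invalid_image_error", "'binary' must be a logical matrix")
  }
  runs <- lapply(seq_len(ncol(binary)), function(j) {
    r <- rle(binary[, j])
    list(bright = r$values, lengths = r$lengths)
  })
  structure(runs, class = "column_runs",
            height = nrow(binary), n_columns = ncol(binary))
}

#' Majority first-pixel color
#'
#' The color (bright/dark) that begins the greater number of columns;
#' an exact tie resolves to bright.
#'
#' @param runs A `column_runs` object.
#' @return `"bright"` or `"dark"`.
#' @export
majority_first_color <- function(runs) {
  if (length(runs) == 0L) {
    .lamella_stop("invalid_image_error", "no columns to inspect")
  }
  firsts <- vapply(runs, function(r) r$bright[1], logical(1))
  if (sum(firsts) >= sum(!firsts)) "bright" else "dark"
}

#' Column quality filter
#'
#' Applies the two rejection rules: a column is retained iff (a) its first
#' pixel has the majority first color, and (b) it contains exactly the
#' expected number of bright and dark lamellae.  When
#' `drop_partial_bottom` is `TRUE` (default) and a column has exactly one
#' run more than expected, its final run -- the band cut off by the bottom
#' of the frame, which the operator is told not to count -- is ignored both
#' here and in measurement.
#'
#' @param runs A `column_runs` object.
#' @param n_bright,n_dark Operator-counted numbers of bright and dark
#'   lamellae in the measurement area.
#' @param first Majority first color, from [majority_first_color()].
#' @param drop_partial_bottom Ignore a single surplus bottom-edge run.
#' @return Logical retained-mask over columns, with attributes
#'   `rejected_first_color` and `rejected_count` (logical vectors recording
#'   which rule rejected each column).
#' @export
filter_columns <- function(runs, n_bright, n_dark,
                           first = majority_first_color(runs),
                           drop_partial_bottom = TRUE) {
  .validate_expected_counts(n_bright, n_dark)
  want_bright <- identical(first, "bright")
  bad_first <- vapply(runs, function(r) r$bright[1] != want_bright, logical(1))
  bad_count <- vapply(runs, function(r) {
    kept <- .kept_runs(r, n_bright, n_dark, drop_partial_bottom)
    sum(kept$bright) != n_bright || sum(!kept$bright) != n_dark
  }, logical(1))
  mask <- !bad_first & !bad_count
  if (!any(mask)) {
    .lamella_stop("all_columns_rejected_error",
                  sprintf(paste0("every column was rejected (%d by first-pixel color, %d by lamella count); ",
                                 "re-count the bright/dark lamellae in the measurement area or re-check the ROI"),
                          sum(bad_first), sum(bad_count & !bad_first)))
  }
  attr(mask, "rejected_first_color") <- bad_first
  attr(mask, "rejected_count") <- bad_count
  mask
}

# Drop a single surplus final run (it always touches the bottom edge).
.kept_runs <- function(r, n_bright, n_dark, drop_partial_bottom) {
  n <- length(r$lengths)
  if (drop_partial_bottom && n == n_bright + n_dark + 1L) {
    list(bright = r$bright[-n], lengths = r$lengths[-n])
  } else {
    r
  }
}

#' Average lamellar thicknesses over retained columns
#'
#' For each lamella (positionally: the i-th bright run corresponds across
#' retained columns, likewise dark), averages its pixel thickness over all
#' retained columns and converts to micrometers with the supplied
#' calibration.
#'
#' @param runs A `column_runs` object.
#' @param mask Logical retained-column mask from [filter_columns()].
#' @param n_bright,n_dark Expected lamella counts.
#' @param pixel_length_um Physical length of one pixel in micrometers;
#'   default 0.3185 (20x magnification on the reference setup).
#' @param drop_partial_bottom Must match the value used in
#'   [filter_columns()].
#' @return An object of class `lamellar_measurement`; see
#'   [measure_lamellae()] for its contents.
#' @export
average_thicknesses <- function(runs, mask, n_bright, n_dark,
                                pixel_length_um = 0.3185,
                                drop_partial_bottom = TRUE) {
  .validate_expected_counts(n_bright, n_dark)
  if (length(mask) != length(runs)) {
    .lamella_stop("invalid_image_error", "mask length must equal the number of columns")
  }
  if (!any(mask)) {
    .lamella_stop("all_columns_rejected_error", "no retained columns to average")
  }
  if (pixel_length_um <= 0) {
    .lamella_stop("invalid_config_error", "'pixel_length_um' must be > 0")
  }
  bright_sum <- numeric(n_bright)
  dark_sum <- numeric(n_dark)
  idx <- which(mask)
  for (j in idx) {
    kept <- .kept_runs(runs[[j]], n_bright, n_dark, drop_partial_bottom)
    bl <- kept$lengths[kept$bright]
    dl <- kept$lengths[!kept$bright]
    if (length(bl) != n_bright || length(dl) != n_dark) {
      .lamella_stop("invalid_image_error",
                    sprintf("retained column %d does not have the expected lamella counts; filter first", j))
    }
    bright_sum <- bright_sum + bl
    dark_sum <- dark_sum + dl
  }
  ng <- length(idx)
  new_lamellar_measurement(
    avg_bright_um = bright_sum / ng * pixel_length_um,
    avg_dark_um = dark_sum / ng * pixel_length_um,
    n_sets = length(runs),
    ng_sets = ng,
    retained_mask = as.logical(mask),
    pixel_length_um = pixel_length_um,
    n_bright = as.integer(n_bright),
    n_dark = as.integer(n_dark)
  )
}

# Internal constructor; extra fields (diagnostics attached by the pipeline)
# are passed through.
new_lamellar_measurement <- function(avg_bright_um, avg_dark_um, n_sets, ng_sets,
                                     retained_mask, pixel_length_um,
                                     n_bright, n_dark, ...) {
  structure(list(avg_bright_um = avg_bright_um,
                 avg_dark_um = avg_dark_um,
                 n_sets = n_sets,
                 ng_sets = ng_sets,
                 retained_mask = retained_mask,
                 pixel_length_um = pixel_length_um,
                 n_bright = n_bright,
                 n_dark = n_dark,
                 ...),
            class = "lamellar_measurement")
}
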