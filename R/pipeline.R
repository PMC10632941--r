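# The end-to-end pipeline and the lamellar_measurement S3 class.

#' Measure lamellar thicknesses in an annotated micrograph
#'
#' Runs the full measurement pipeline on an operator-annotated
#' polarized-light micrograph: detect the corner fiducials, rotate so the
#' lamellae run horizontally, crop to the yellow rectangle interior,
#' convert to grayscale and stretch contrast, binarize each pixel against
#' its column-local mean, repair floating pixels, run-length encode every
#' column, reject columns failing the first-pixel-color or lamella-count
#' rules, and average each lamella's thickness (in micrometers) over the
#' retained columns.
#'
#' @param image Path to a lossless TIFF/PNG, an H x W x 3 RGB array
#'   (0..255), or a `lamellar_fixture` from [generate_fixture()].
#' @param n_bright,n_dark Operator-counted numbers of bright and dark
#'   lamellae in the measurement area (counting stops at a band mostly cut
#'   off by the bottom of the frame).
#' @param pixel_length_um Physical pixel size in micrometers; default
#'   0.3185, the 20x calibration of the reference setup.
#' @param colors A [marker_colors()] object.
#' @param params A [threshold_params()] object.
#' @param drop_partial_bottom Ignore a single surplus bottom-edge band per
#'   column (see [filter_columns()]).
#' @param output_dir If non-`NULL`, write the six diagnostic stage images
#'   (`stage_1_annotated.png` .. `stage_6_retained.png`) plus
#'   `results.csv` and `results.json` there.
#' @param verbose Print progress diagnostics (detected angle, crop bounds,
#'   rejection tallies).
#' @return An object of class `lamellar_measurement`: a list with
#'   `avg_bright_um`, `avg_dark_um` (per-lamella average thicknesses),
#'   `n_sets` (total columns), `ng_sets` (retained columns),
#'   `retained_mask`, `pixel_length_um`, `n_bright`, `n_dark`, plus
#'   diagnostics `rotation_deg`, `crop_bounds`, `rejections`, `first_color`
#'   and the repaired `binary` image.  Methods: `print`, `summary`,
#'   `as.data.frame`, `plot`.
#' @examples
#' fx <- generate_fixture(fixture_spec())
#' m <- measure_lamellae(fx, n_bright = 4, n_dark = 3)
#' m
#' @export
measure_lamellae <- function(image, n_bright, n_dark,
                             pixel_length_um = 0.3185,
                             colors = marker_colors(),
                             params = threshold_params(),
                             drop_partial_bottom = TRUE,
                             output_dir = NULL,
                             verbose = FALSE) {
  .validate_expected_counts(n_bright, n_dark)
  img <- .resolve_image(image)
  pre <- .preprocess(img, colors, verbose)
  bin <- .binarize(pre$cropped, params)
  runs <- run_length_encode(bin$fixed)
  first <- majority_first_color(runs)
  mask <- filter_columns(runs, n_bright, n_dark, first, drop_partial_bottom)
  res <- average_thicknesses(runs, mask, n_bright, n_dark,
                             pixel_length_um, drop_partial_bottom)
  res$first_color <- first
  res$rotation_deg <- pre$angle
  res$crop_bounds <- attr(pre$cropped, "crop_bounds")
  res$rejections <- c(first_color = sum(attr(mask, "rejected_first_color")),
                      count = sum(attr(mask, "rejected_count") &
                                    !attr(mask, "rejected_first_color")))
  res$binary <- bin$fixed
  res$call <- match.call()
  if (verbose) {
    message(sprintf("retained %d of %d columns (rejected: %d first-color, %d count)",
                    res$ng_sets, res$n_sets, res$rejections[["first_color"]],
                    res$rejections[["count"]]))
  }
  if (!is.null(output_dir)) {
    .write_stage_images(output_dir, img, pre, bin, res)
    write_results(res, output_dir)
  }
  res
}

.resolve_image <- function(image) {
  if (inherits(image, "lamellar_fixture")) return(image$image)
  if (is.character(image)) return(read_annotated_image(image))
  .assert_rgb(image)
  image
}

.preprocess <- function(img, colors, verbose = FALSE) {
  markers <- detect_markers(img, colors)
  angle <- compute_rotation_angle(markers)
  rotated <- rotate_image(img, angle)
  cropped <- crop_to_roi(rotated, colors)
  if (verbose) {
    b <- attr(cropped, "crop_bounds")
    message(sprintf("corrective rotation %.3f deg; crop rows %d..%d, cols %d..%d",
                    angle, b[["top"]], b[["bottom"]], b[["left"]], b[["right"]]))
  }
  list(markers = markers, angle = angle, rotated = rotated, cropped = cropped)
}

.binarize <- function(cropped, params) {
  gray <- to_grayscale(cropped)
  stretched <- stretch_contrast(gray, params)
  raw <- binarize_columns(stretched, params)
  fixed <- fix_floating_pixels(raw, params)
  list(gray = gray, stretched = stretched, raw = raw, fixed = fixed)
}

.write_stage_images <- function(dir, img, pre, bin, res) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image_png(img, file.path(dir, "stage_1_annotated.png"))
  write_image_png(pre$rotated, file.path(dir, "stage_2_rotated.png"))
  write_image_png(pre$cropped, file.path(dir, "stage_3_cropped.png"))
  write_image_png(bin$stretched, file.path(dir, "stage_4_grayscale.png"))
  write_image_png(bin$fixed, file.path(dir, "stage_5_binary.png"))
  write_image_png(.retained_image(res), file.path(dir, "stage_6_retained.png"))
  invisible(dir)
}

# Final-stage figure: binary image with rejected columns grayed out.
.retained_image <- function(m) {
  img <- matrix(as.numeric(m$binary) * 255, nrow(m$binary), ncol(m$binary))
  img[, !m$retained_mask] <- 128
  img
}

#' Binarized preview for counting lamellae
#'
#' Runs only the preprocessing and binarization stages and returns the
#' binary measurement image the operator uses to count the bright and dark
#' bands before setting the expected counts.  Printing the result restates
#' the counting rules.
#'
#' @inheritParams measure_lamellae
#' @param output_path If non-`NULL`, write the preview PNG there.
#' @return Logical matrix of class `lamellar_preview` (`TRUE` = bright).
#' @export
count_assist <- function(image, colors = marker_colors(),
                         params = threshold_params(),
                         output_path = NULL, verbose = FALSE) {
  img <- .resolve_image(image)
  pre <- .preprocess(img, colors, verbose)
  bin <- .binarize(pre$cropped, params)
  if (!is.null(output_path)) write_image_png(bin$fixed, output_path)
  structure(bin$fixed, class = c("lamellar_preview", "matrix", "array"))
}

#' @export
print.lamellar_preview <- function(x, ...) {
  cat(sprintf("Binary counting preview: %d x %d px\n", nrow(x), ncol(x)))
  cat("Counting rules:\n")
  cat("  - start from the band matching the majority color of the top pixel row\n")
  cat("  - count bright and dark bands from the top down\n")
  cat("  - stop at a band mostly cut off by the bottom of the frame\n")
  invisible(x)
}

#' @export
print.lamellar_measurement <- function(x, digits = 4, ...) {
  cat("Lamellar thickness measurement\n")
  cat(sprintf("  columns: %d retained of %d (pixel length %.4f um)\n",
              x$ng_sets, x$n_sets, x$pixel_length_um))
  cat(sprintf("  bright lamellae (um): %s\n",
              paste(formatC(x$avg_bright_um, digits = digits, format = "f"), collapse = " ")))
  cat(sprintf("  dark lamellae (um):   %s\n",
              paste(formatC(x$avg_dark_um, digits = digits, format = "f"), collapse = " ")))
  invisible(x)
}

#' @export
summary.lamellar_measurement <- function(object, ...) {
  print(object)
  if (!is.null(object$rotation_deg)) {
    cat(sprintf("  corrective rotation: %.3f deg\n", object$rotation_deg))
  }
  if (!is.null(object$rejections)) {
    cat(sprintf("  rejected columns: %d by first-pixel color, %d by lamella count\n",
                object$rejections[["first_color"]], object$rejections[["count"]]))
  }
  cat(sprintf("  mean bright: %.4f um; mean dark: %.4f um\n",
              mean(object$avg_bright_um), mean(object$avg_dark_um)))
  invisible(object)
}

#' @export
as.data.frame.lamellar_measurement <- function(x, ...) {
  data.frame(
    lamella = c(seq_along(x$avg_bright_um), seq_along(x$avg_dark_um)),
    color = rep(c("bright", "dark"), c(x$n_bright, x$n_dark)),
    avg_thickness_um = c(x$avg_bright_um, x$avg_dark_um),
    avg_thickness_px = c(x$avg_bright_um, x$avg_dark_um) / x$pixel_length_um,
    n_sets = x$n_sets,
    ng_sets = x$ng_sets
  )
}

#' Plot the final measurement image
#'
#' Displays the binary measurement image with rejected columns grayed out
#' (the sixth diagnostic stage).
#'
#' @param x A `lamellar_measurement` with its `binary` component (as
#'   returned by [measure_lamellae()]).
#' @param ... Passed to [graphics::rasterImage()] (unused).
#' @export
plot.lamellar_measurement <- function(x, ...) {
  if (is.null(x$binary)) {
    .lamella_stop("invalid_image_error", "this measurement carries no binary image to plot")
  }
  img <- .retained_image(x) / 255
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1), asp = nrow(img) / ncol(img))
  graphics::rasterImage(img, 0, 0, 1, 1, interpolate = FALSE)
  graphics::title(sprintf("Retained columns: %d of %d", x$ng_sets, x$n_sets))
  invisible(x)
}

#' Write measurement results
#'
#' Writes `results.csv` (one row per lamella) and `results.json` (the full
#' measurement record) to a directory.
#'
#' @param m A `lamellar_measurement`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(m), file.path(dir, "results.csv"), row.names = FALSE)
  rec <- list(avg_bright_um = round(m$avg_bright_um, 4),
              avg_dark_um = round(m$avg_dark_um, 4),
              n_sets = m$n_sets,
              ng_sets = m$ng_sets,
              retained_mask = m$retained_mask,
              pixel_length_um = m$pixel_length_um,
              n_bright = m$n_bright,
              n_dark = m$n_dark)
  jsonlite::write_json(rec, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read measurement results back from JSON
#'
#' Reconstructs a `lamellar_measurement` (without the binary image) from a
#' `results.json` written by [write_results()].
#'
#' @param path Path to `results.json`.
#' @return A `lamellar_measurement` object.
#' @export
read_results <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_lamellar_measurement(
    avg_bright_um = as.numeric(rec$avg_bright_um),
    avg_dark_um = as.numeric(rec$avg_dark_um),
    n_sets = as.integer(rec$n_sets),
    ng_sets = as.integer(rec$ng_sets),
    retained_mask = as.logical(rec$retained_mask),
    pixel_length_um = as.numeric(rec$pixel_length_um),
    n_bright = as.integer(rec$n_bright),
    n_dark = as.integer(rec$n_dark)
  )
}
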