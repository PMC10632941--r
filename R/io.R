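#' Read an annotated micrograph
#'
#' Loads a lossless TIFF or PNG raster as an H x W x 3 array of 8-bit RGB
#' values.  Lossless formats are required because the fiducial markers are
#' matched by exact RGB value; JPEG-style compression would destroy them.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return Numeric H x W x 3 array with values in 0..255 and attribute
#'   `source_path`.
#' @export
read_annotated_image <- function(path) {
  if (!file.exists(path)) {
    .lamella_stop("invalid_image_error", sprintf("file not found: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    .lamella_stop("invalid_image_error",
                  sprintf("unsupported image format '.%s' (use lossless TIFF or PNG)", ext))
  )
  img <- .as_rgb255(raw)
  attr(img, "source_path") <- path
  img
}

# Normalize readTIFF/readPNG output (0..1 doubles, possibly gray or RGBA)
# to an H x W x 3 array of 0..255 values.
.as_rgb255 <- function(raw) {
  if (is.matrix(raw)) {
    raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  }
  if (length(dim(raw)) != 3L) {
    .lamella_stop("invalid_image_error", "image must be a 2-D raster")
  }
  if (dim(raw)[3] >= 4L) raw <- raw[, , 1:3, drop = FALSE]
  if (dim(raw)[3] == 2L) raw <- array(rep(raw[, , 1], 3L), dim = c(dim(raw)[1:2], 3L))
  .round_half_up(raw * 255)
}

#' Write an image stage as PNG
#'
#' Writes an RGB array (0..255) or a grayscale/binary matrix as a PNG file,
#' used for the diagnostic stage figures.
#'
#' @param image H x W x 3 array in 0..255, a numeric matrix in 0..255, or a
#'   logical matrix (TRUE rendered white).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  if (is.logical(image)) image <- matrix(as.numeric(image) * 255, nrow(image), ncol(image))
  png::writePNG(image / 255, target = path)
  invisible(path)
}
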