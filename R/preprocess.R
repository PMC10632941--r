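# Stage 1: fiducial detection, reorientation, and crop to the yellow ROI.

#' Detect the red and green corner fiducials
#'
#' Finds the pixels matching the red (top-corner) and green (bottom-corner)
#' marker colors, groups them into 8-connected components (hand-placed
#' markers may span more than one pixel), and returns each component's
#' centroid rounded to the nearest pixel.  Exactly two components of each
#' color are required.  Red points are ordered top-first: smaller row index,
#' ties broken by smaller column.
#'
#' @param image H x W x 3 RGB array (0..255), e.g. from
#'   [read_annotated_image()].
#' @param colors A [marker_colors()] object.
#' @return A list of class `marker_set` with `red_points` and `green_points`,
#'   each a 2 x 2 matrix of (row, col) pixel coordinates.
#' @export
detect_markers <- function(image, colors = marker_colors()) {
  .assert_rgb(image)
  red <- .marker_centroids(image, colors$red, colors$tolerance, "red")
  green <- .marker_centroids(image, colors$green, colors$tolerance, "green")
  red <- red[order(red[, 1], red[, 2]), , drop = FALSE]
  green <- green[order(green[, 1], green[, 2]), , drop = FALSE]
  structure(list(red_points = red, green_points = green), class = "marker_set")
}

.marker_centroids <- function(image, rgb, tolerance, name) {
  mask <- .color_mask(image, rgb, tolerance)
  n <- sum(mask)
  if (n == 0L) {
    .lamella_stop("missing_marker_error",
                  sprintf("no pixel matches the %s marker color (%s); the image may have been re-encoded lossily",
                          name, paste(rgb, collapse = ",")))
  }
  if (n > 2000L) {
    .lamella_stop("ambiguous_marker_error",
                  sprintf("%d pixels match the %s marker color; markers must be small corner dots", n, name))
  }
  coords <- which(mask, arr.ind = TRUE)
  labs <- .label_components8(coords)
  k <- max(labs)
  if (k < 2L) {
    .lamella_stop("missing_marker_error",
                  sprintf("found %d %s marker(s); exactly 2 are required (one per corner)", k, name))
  }
  if (k > 2L) {
    .lamella_stop("ambiguous_marker_error",
                  sprintf("found %d %s markers; exactly 2 are required", k, name))
  }
  pts <- t(vapply(seq_len(k), function(i) {
    .round_half_up(colMeans(coords[labs == i, , drop = FALSE]))
  }, numeric(2)))
  colnames(pts) <- c("row", "col")
  pts
}

# 8-connectivity labelling by pairwise Chebyshev adjacency and label
# propagation; marker blobs are tiny so the quadratic pass is immaterial.
.label_components8 <- function(coords) {
  n <- nrow(coords)
  labs <- seq_len(n)
  if (n == 1L) return(labs)
  adj <- abs(outer(coords[, 1], coords[, 1], "-")) <= 1L &
    abs(outer(coords[, 2], coords[, 2], "-")) <= 1L
  repeat {
    new <- apply(adj, 1L, function(a) min(labs[a]))
    if (identical(new, labs)) break
    labs <- new
  }
  match(labs, sort(unique(labs)))
}

#' Corrective rotation angle from the red fiducials
#'
#' Computes the rotation, in degrees counterclockwise as displayed, that
#' brings the two red (top-corner) markers onto the same pixel row while
#' keeping the red markers above the green ones.  Of the two rotations that
#' level the red pair (180 degrees apart) the one satisfying red-above-green
#' is returned; ties go to the smaller magnitude.
#'
#' @param markers A `marker_set` from [detect_markers()].
#' @return Rotation angle in degrees, in (-180, 180].
#' @export
compute_rotation_angle <- function(markers) {
  p <- markers$red_points
  g <- markers$green_points
  dr <- p[2, 1] - p[1, 1]
  dc <- p[2, 2] - p[1, 2]
  if (dr == 0 && dc == 0) {
    .lamella_stop("degenerate_marker_error", "the two red markers coincide; cannot derive an angle")
  }
  base <- atan2(dr, dc) * 180 / pi
  cand <- vapply(c(base, base - 180), .normalize_angle, numeric(1))
  ok <- vapply(cand, function(a) .red_above_green(p, g, a), logical(1))
  chosen <- cand[ok]
  if (length(chosen) == 0L) chosen <- cand  # degenerate marker layout; keep leveling anyway
  unname(chosen[which.min(abs(chosen))])
}

.normalize_angle <- function(a) {
  a <- a %% 360
  if (a > 180) a <- a - 360
  a
}

# After rotating by `degrees` (visual CCW), do the red points sit above green?
.red_above_green <- function(red, green, degrees) {
  rad <- degrees * pi / 180
  rot_row <- function(pts) -sin(rad) * pts[, 2] + cos(rad) * pts[, 1]
  mean(rot_row(red)) < mean(rot_row(green))
}

#' Rotate an annotated image
#'
#' Rotates the image by `degrees` counterclockwise (as displayed, origin at
#' the top-left) about its center, onto a canvas enlarged to contain the
#' rotated content.  Resampling is nearest-neighbor so the exact marker RGB
#' codes survive; uncovered canvas is filled black.
#'
#' @param image H x W x 3 RGB array (0..255).
#' @param degrees Rotation angle in degrees, counterclockwise-positive.
#' @return The rotated RGB array.
#' @export
rotate_image <- function(image, degrees) {
  .assert_rgb(image)
  if (degrees %% 360 == 0) return(image)
  h <- dim(image)[1]
  w <- dim(image)[2]
  rad <- degrees * pi / 180
  ct <- cos(rad)
  st <- sin(rad)
  cr <- (h + 1) / 2
  cc <- (w + 1) / 2
  corn_c <- c(1, w, 1, w) - cc
  corn_r <- c(1, 1, h, h) - cr
  # forward map (visual CCW): c' = ct*c + st*r ; r' = -st*c + ct*r
  out_w <- 2L * ceiling(max(abs(ct * corn_c + st * corn_r))) + 1L
  out_h <- 2L * ceiling(max(abs(-st * corn_c + ct * corn_r))) + 1L
  cr2 <- (out_h + 1) / 2
  cc2 <- (out_w + 1) / 2
  cc_g <- matrix(seq_len(out_w) - cc2, out_h, out_w, byrow = TRUE)
  rc_g <- matrix(seq_len(out_h) - cr2, out_h, out_w)
  ci <- .round_half_up(ct * cc_g - st * rc_g + cc)
  ri <- .round_half_up(st * cc_g + ct * rc_g + cr)
  ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
  idx <- (ci[ok] - 1) * h + ri[ok]
  out <- array(0, dim = c(out_h, out_w, 3L))
  for (k in 1:3) {
    ch <- matrix(0, out_h, out_w)
    src <- image[, , k]
    ch[ok] <- src[idx]
    out[, , k] <- ch
  }
  attr(out, "rotation_deg") <- degrees
  out
}

#' Crop to the interior of the yellow rectangle
#'
#' Locates the yellow rectangle in an already-reoriented image and returns
#' the sub-image strictly inside its innermost yellow rows and columns.
#' A row (column) counts as yellow when at least half of its span across the
#' rectangle's bounding box matches the yellow code, which tolerates the
#' small perforations nearest-neighbor rotation leaves in thin lines.  Any
#' residual marker-colored pixel inside the crop (annotation bleed scattered
#' by the rotation) is replaced by the nearest non-marker pixel value in its
#' column, so the result is marker-free.
#'
#' @param image H x W x 3 RGB array, already rotated so the rectangle is
#'   axis-aligned.
#' @param colors A [marker_colors()] object.
#' @return The interior RGB array, with attributes `crop_bounds`
#'   (named vector top/bottom/left/right of the interior, in rotated-image
#'   coordinates) and `origin_note`.
#' @export
crop_to_roi <- function(image, colors = marker_colors()) {
  .assert_rgb(image)
  b <- .roi_interior(image, colors)
  rows <- b$rows
  cols <- b$cols
  interior <- image[rows, cols, , drop = FALSE]
  interior <- .repair_annotation_bleed(interior, colors)
  attr(interior, "crop_bounds") <- c(top = rows[1], bottom = rows[length(rows)],
                                     left = cols[1], right = cols[length(cols)])
  attr(interior, "origin_note") <- sprintf(
    "interior rows %d..%d, cols %d..%d of the rotated image",
    rows[1], rows[length(rows)], cols[1], cols[length(cols)])
  interior
}

# Row/column index ranges strictly inside the innermost yellow rows and
# columns.  A row (column) qualifies as yellow when >= 50% of its span
# across the yellow bounding box matches the yellow code.
.roi_interior <- function(image, colors) {
  ymask <- .color_mask(image, colors$yellow, colors$tolerance)
  if (!any(ymask)) {
    .lamella_stop("missing_roi_error",
                  sprintf("no pixel matches the yellow rectangle color (%s)",
                          paste(colors$yellow, collapse = ",")))
  }
  yr <- range(which(rowSums(ymask) > 0))
  yc <- range(which(colSums(ymask) > 0))
  span_w <- yc[2] - yc[1] + 1
  span_h <- yr[2] - yr[1] + 1
  row_frac <- rowSums(ymask[, yc[1]:yc[2], drop = FALSE]) / span_w
  col_frac <- colSums(ymask[yr[1]:yr[2], , drop = FALSE]) / span_h
  qrow <- which(row_frac >= 0.5)
  qcol <- which(col_frac >= 0.5)
  crow <- mean(yr)
  ccol <- mean(yc)
  top <- suppressWarnings(max(qrow[qrow <= crow]))
  bottom <- suppressWarnings(min(qrow[qrow >= crow]))
  left <- suppressWarnings(max(qcol[qcol <= ccol]))
  right <- suppressWarnings(min(qcol[qcol >= ccol]))
  if (!is.finite(top) || !is.finite(bottom) || !is.finite(left) || !is.finite(right) ||
      bottom - top < 2 || right - left < 2) {
    .lamella_stop("malformed_roi_error",
                  "the yellow rectangle has an empty interior; check the annotation")
  }
  list(rows = (top + 1):(bottom - 1), cols = (left + 1):(right - 1))
}

# Replace marker-colored pixels inside the crop by the nearest non-marker
# pixel value in the same column.
.repair_annotation_bleed <- function(interior, colors) {
  bad <- .color_mask(interior, colors$yellow, colors$tolerance) |
    .color_mask(interior, colors$red, colors$tolerance) |
    .color_mask(interior, colors$green, colors$tolerance)
  if (!any(bad)) return(interior)
  h <- nrow(bad)
  idx <- which(bad, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]
    cl <- idx[i, 2]
    good_rows <- which(!bad[, cl])
    if (length(good_rows) == 0L) {
      .lamella_stop("malformed_roi_error",
                    "a cropped column consists entirely of marker-colored pixels")
    }
    src <- good_rows[which.min(abs(good_rows - r))]
    interior[r, cl, ] <- interior[src, cl, ]
  }
  interior
}
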