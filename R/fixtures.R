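# Synthetic annotated micrographs with ground truth.  The study's real
# polarized-light images are confidential, so validation runs on generated
# scenes: alternating bright/dark horizontal bands of known thickness,
# optional global rotation, Gaussian intensity noise, and blob defects
# emulating osteocyte lacunae, annotated exactly as the measurement
# protocol prescribes (yellow rectangle, red top corners, green bottom
# corners).

#' Specify a synthetic lamellar fixture
#'
#' @param band_thicknesses Integer vector of band thicknesses in pixels,
#'   top to bottom; colors alternate starting with `first_color`.  The
#'   default lays out 4 bright and 3 dark lamellae, the protocol's worked
#'   counting example.
#' @param first_color Color of the topmost band, `"bright"` or `"dark"`.
#' @param width Content (ROI interior) width in pixels.
#' @param bright_intensity,dark_intensity 8-bit gray levels of the two band
#'   classes; they must differ by at least 40 when noise is added so the
#'   bands stay separable.
#' @param rotation_deg Global rotation applied to the whole scene
#'   (counterclockwise as displayed); the annotation rectangle is aligned
#'   with the bands, so the pipeline must undo this rotation.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise
#'   on the banded content (0 = noiseless).
#' @param defects List of blobs, each `list(center = c(row, col), radius,
#'   intensity)` in ROI-interior pixel coordinates, emulating osteocyte
#'   lacunae.
#' @param roi_margin Padding in pixels between the rectangle and the canvas
#'   edge.
#' @param seed RNG seed recorded in the ground truth.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(band_thicknesses = c(5L, 4L, 6L, 4L, 5L, 4L, 7L),
                         first_color = c("bright", "dark"),
                         width = 120L,
                         bright_intensity = 200,
                         dark_intensity = 60,
                         rotation_deg = 0,
                         noise_sd = 0,
                         defects = list(),
                         roi_margin = 12L,
                         seed = 1L) {
  first_color <- match.arg(first_color)
  if (length(band_thicknesses) < 1L || any(band_thicknesses < 1) ||
      any(band_thicknesses != as.integer(band_thicknesses))) {
    .lamella_stop("fixture_spec_error", "band thicknesses must be integers >= 1")
  }
  if (width < 4L) {
    .lamella_stop("fixture_spec_error", "'width' must be >= 4")
  }
  if (noise_sd < 0) {
    .lamella_stop("fixture_spec_error", "'noise_sd' must be >= 0")
  }
  if (noise_sd > 0 && abs(bright_intensity - dark_intensity) < 40) {
    .lamella_stop("fixture_spec_error",
                  "bright and dark intensities must differ by >= 40 when noise is added")
  }
  if (any(c(bright_intensity, dark_intensity) < 0) ||
      any(c(bright_intensity, dark_intensity) > 255)) {
    .lamella_stop("fixture_spec_error", "intensities must lie in 0..255")
  }
  for (d in defects) {
    if (!is.list(d) || length(d$center) != 2L || is.null(d$radius) || is.null(d$intensity)) {
      .lamella_stop("fixture_spec_error",
                    "each defect must be list(center = c(row, col), radius, intensity)")
    }
  }
  if (roi_margin < 1L) {
    .lamella_stop("fixture_spec_error", "'roi_margin' must be >= 1")
  }
  structure(list(band_thicknesses = as.integer(band_thicknesses),
                 first_color = first_color,
                 width = as.integer(width),
                 bright_intensity = bright_intensity,
                 dark_intensity = dark_intensity,
                 rotation_deg = rotation_deg,
                 noise_sd = noise_sd,
                 defects = defects,
                 roi_margin = as.integer(roi_margin),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate an annotated synthetic micrograph with ground truth
#'
#' Renders the banded scene analytically: every canvas pixel center is
#' back-rotated into the band frame and classified there, so band edges are
#' geometrically exact at any rotation (this is scene generation, not the
#' resampling under test).  Defects are stamped, noise added, and the
#' 2-pixel yellow rectangle with exact-color corner fiducials is drawn
#' last, aligned with the bands.  Deterministic given the spec's seed.
#'
#' @param spec A [fixture_spec()] object.
#' @return A list of class `lamellar_fixture` with `image` (annotated
#'   H x W x 3 array) and `truth` (band mask, per-band thicknesses and
#'   colors, expected counts, marker coordinates, ROI size, content bounds
#'   when unrotated, seed).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  th <- spec$band_thicknesses
  n_band <- length(th)
  band_bright <- (seq_len(n_band) %% 2L == 1L) == (spec$first_color == "bright")
  hc <- sum(th)
  wc <- spec$width
  cy <- hc / 2
  cx <- wc / 2
  rad <- spec$rotation_deg * pi / 180
  ct <- cos(rad)
  st <- sin(rad)
  ey <- hc / 2 + 2
  ex <- wc / 2 + 2
  h2 <- 2L * ceiling(abs(ct) * ey + abs(st) * ex) + 2L * spec$roi_margin
  w2 <- 2L * ceiling(abs(ct) * ex + abs(st) * ey) + 2L * spec$roi_margin
  if ((h2 - hc) %% 2L != 0L) h2 <- h2 + 1L  # keep pixel centers aligned to band cells at theta = 0
  if ((w2 - wc) %% 2L != 0L) w2 <- w2 + 1L

  cc_g <- matrix(seq_len(w2) - (w2 + 1) / 2, h2, w2, byrow = TRUE)
  rc_g <- matrix(seq_len(h2) - (h2 + 1) / 2, h2, w2)
  xb <- ct * cc_g - st * rc_g + cx
  yb <- st * cc_g + ct * rc_g + cy
  ib <- floor(yb)
  jb <- floor(xb)
  inside <- ib >= 0 & ib < hc & jb >= 0 & jb < wc

  bounds <- c(0, cumsum(th))
  img <- matrix(0, h2, w2)
  bi <- findInterval(ib[inside] + 0.5, bounds)
  img[inside] <- ifelse(band_bright[bi], spec$bright_intensity, spec$dark_intensity)

  for (d in spec$defects) {
    y0 <- d$center[1] - 0.5
    x0 <- d$center[2] - 0.5
    if (d$center[1] - d$radius < 0 || d$center[1] + d$radius > hc ||
        d$center[2] - d$radius < 0 || d$center[2] + d$radius > wc) {
      .lamella_stop("fixture_spec_error", "defect blob extends outside the ROI content")
    }
    hit <- inside & ((yb - y0)^2 + (xb - x0)^2 <= d$radius^2)
    img[hit] <- d$intensity
  }

  set.seed(spec$seed)
  if (spec$noise_sd > 0) {
    img[inside] <- img[inside] + stats::rnorm(sum(inside), 0, spec$noise_sd)
  }
  img <- .clamp(.round_half_up(img), 0, 255)

  ring <- ib >= -2 & ib < hc + 2 & jb >= -2 & jb < wc + 2 & !inside
  chr <- img; chg <- img; chb <- img
  chr[ring] <- 255
  chg[ring] <- 255
  chb[ring] <- 0

  image <- array(0, dim = c(h2, w2, 3L))
  image[, , 1] <- chr
  image[, , 2] <- chg
  image[, , 3] <- chb

  # corner fiducials at the outer ring cell centers, stamped after the scene
  fwd <- function(y, x) {
    c(row = .round_half_up(-st * (x - cx) + ct * (y - cy) + (h2 + 1) / 2),
      col = .round_half_up(ct * (x - cx) + st * (y - cy) + (w2 + 1) / 2))
  }
  red_pts <- rbind(fwd(-1.5, -1.5), fwd(-1.5, wc + 1.5))
  green_pts <- rbind(fwd(hc + 1.5, -1.5), fwd(hc + 1.5, wc + 1.5))
  red_pts <- red_pts[order(red_pts[, 1], red_pts[, 2]), , drop = FALSE]
  green_pts <- green_pts[order(green_pts[, 1], green_pts[, 2]), , drop = FALSE]
  cols <- marker_colors()
  for (i in 1:2) {
    image[red_pts[i, 1], red_pts[i, 2], ] <- cols$red
    image[green_pts[i, 1], green_pts[i, 2], ] <- cols$green
  }

  band_mask <- matrix(rep(rep(band_bright, times = th), times = wc), hc, wc)
  content <- NULL
  if (spec$rotation_deg %% 360 == 0) {
    r0 <- (h2 - hc) / 2L
    c0 <- (w2 - wc) / 2L
    content <- list(rows = (r0 + 1L):(r0 + hc), cols = (c0 + 1L):(c0 + wc))
  }

  truth <- list(thickness_px = th,
                band_bright = band_bright,
                n_bright = sum(band_bright),
                n_dark = sum(!band_bright),
                roi_height = hc,
                roi_width = wc,
                band_mask = band_mask,
                red_points = red_pts,
                green_points = green_pts,
                rotation_deg = spec$rotation_deg,
                content = content,
                defects = spec$defects,
                bright_intensity = spec$bright_intensity,
                dark_intensity = spec$dark_intensity,
                seed = spec$seed)
  structure(list(image = image, truth = truth, spec = spec),
            class = "lamellar_fixture")
}

#' Stamp a blob defect into an annotated image
#'
#' Sets all pixels within `radius` of `center` (image coordinates) to a
#' uniform gray `intensity`, emulating an osteocyte lacuna.  The blob must
#' lie entirely inside the yellow rectangle's interior of an axis-aligned
#' annotated image.
#'
#' @param image Annotated H x W x 3 array whose yellow rectangle is
#'   axis-aligned (e.g. an unrotated fixture).
#' @param center Numeric `(row, col)` of the blob center, image coordinates.
#' @param radius Blob radius in pixels (0 = single pixel).
#' @param intensity 8-bit gray level stamped into the blob.
#' @param colors A [marker_colors()] object (used to locate the ROI).
#' @return The modified image array.
#' @export
inject_defect <- function(image, center, radius, intensity,
                          colors = marker_colors()) {
  .assert_rgb(image)
  b <- .roi_interior(image, colors)
  if (center[1] - radius < min(b$rows) || center[1] + radius > max(b$rows) ||
      center[2] - radius < min(b$cols) || center[2] + radius > max(b$cols)) {
    .lamella_stop("fixture_spec_error", "defect blob must lie inside the ROI interior")
  }
  rr <- matrix(seq_len(dim(image)[1]), dim(image)[1], dim(image)[2])
  cc <- matrix(seq_len(dim(image)[2]), dim(image)[1], dim(image)[2], byrow = TRUE)
  hit <- (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
  for (k in 1:3) {
    ch <- image[, , k]
    ch[hit] <- intensity
    image[, , k] <- ch
  }
  image
}

#' @export
print.lamellar_fixture <- function(x, ...) {
  t <- x$truth
  cat("Synthetic annotated lamellar micrograph\n")
  cat(sprintf("  canvas: %d x %d px; ROI interior: %d x %d px\n",
              dim(x$image)[1], dim(x$image)[2], t$roi_height, t$roi_width))
  cat(sprintf("  bands: %d bright, %d dark; thicknesses (px): %s\n",
              t$n_bright, t$n_dark, paste(t$thickness_px, collapse = " ")))
  cat(sprintf("  rotation: %g deg; noise sd: %g; defects: %d; seed: %d\n",
              t$rotation_deg, x$spec$noise_sd, length(t$defects), t$seed))
  invisible(x)
}
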