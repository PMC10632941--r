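# Fiducial detection, corrective rotation, and ROI cropping.

test_that("single-pixel fiducials are detected at their exact coordinates", {
  img <- gray_canvas(100, 210, 250)
  img <- set_px(img, 10, 10, c(237, 28, 36))
  img <- set_px(img, 12, 200, c(237, 28, 36))
  img <- set_px(img, 90, 10, c(34, 177, 76))
  img <- set_px(img, 92, 200, c(34, 177, 76))
  ms <- detect_markers(img)
  expect_equal(unname(ms$red_points), rbind(c(10, 10), c(12, 200)))
  expect_equal(unname(ms$green_points), rbind(c(90, 10), c(92, 200)))
})

test_that("multi-pixel marker blobs are grouped and reduced to rounded centroids", {
  img <- gray_canvas(60, 60, 250)
  img <- set_px(img, 10:11, 10:11, c(237, 28, 36))   # 2x2 blob, centroid (10.5, 10.5)
  img <- set_px(img, 10, 50, c(237, 28, 36))
  img <- set_px(img, 50, 10, c(34, 177, 76))
  img <- set_px(img, 50, 50, c(34, 177, 76))
  ms <- detect_markers(img)
  # blob centroid (10.5, 10.5) rounds half-up to (11, 11); top-first ordering
  # puts the single pixel at row 10 before it
  expect_equal(unname(ms$red_points[1, ]), c(10, 50))
  expect_equal(unname(ms$red_points[2, ]), c(11, 11))
})

test_that("missing and ambiguous markers raise classed errors", {
  img <- gray_canvas(50, 50, 250)
  img <- set_px(img, 40, 10, c(34, 177, 76))
  img <- set_px(img, 40, 40, c(34, 177, 76))
  expect_error(detect_markers(img), class = "missing_marker_error")
  img1 <- set_px(img, 5, 25, c(237, 28, 36))  # only one red component
  expect_error(detect_markers(img1), class = "missing_marker_error")
  img3 <- img1
  img3 <- set_px(img3, 5, 5, c(237, 28, 36))
  img3 <- set_px(img3, 5, 45, c(237, 28, 36))
  expect_error(detect_markers(img3), class = "ambiguous_marker_error")
})

test_that("fixture-generated markers are detected at the generator's coordinates", {
  for (theta in c(0, -8, 12)) {
    fx <- generate_fixture(fixture_spec(rotation_deg = theta, seed = 3))
    ms <- detect_markers(fx$image)
    expect_equal(unname(ms$red_points), unname(fx$truth$red_points))
    expect_equal(unname(ms$green_points), unname(fx$truth$green_points))
  }
})

test_that("corrective rotation levels the red pair with red kept above green", {
  mk <- function(red, green) structure(list(red_points = red, green_points = green),
                                       class = "marker_set")
  horiz <- mk(rbind(c(10, 10), c(10, 110)), rbind(c(90, 10), c(90, 110)))
  expect_equal(compute_rotation_angle(horiz), 0)

  tilted <- mk(rbind(c(10, 10), c(20, 110)), rbind(c(90, 10), c(100, 110)))
  expect_equal(compute_rotation_angle(tilted), atan2(10, 100) * 180 / pi, tolerance = 1e-10)

  # vertical red edge: sign resolved by the red-above-green constraint
  vert_right <- mk(rbind(c(10, 10), c(110, 10)), rbind(c(10, 110), c(110, 110)))
  expect_equal(compute_rotation_angle(vert_right), -90)
  vert_left <- mk(rbind(c(10, 110), c(110, 110)), rbind(c(10, 10), c(110, 10)))
  expect_equal(compute_rotation_angle(vert_left), 90)

  upside_down <- mk(rbind(c(90, 10), c(90, 110)), rbind(c(10, 10), c(10, 110)))
  expect_equal(abs(compute_rotation_angle(upside_down)), 180)

  degen <- mk(rbind(c(10, 10), c(10, 10)), rbind(c(90, 10), c(90, 110)))
  expect_error(compute_rotation_angle(degen), class = "degenerate_marker_error")
})

test_that("rotation by zero is the identity and rotation preserves marker colors", {
  fx <- generate_fixture(fixture_spec(seed = 2))
  expect_identical(rotate_image(fx$image, 0), fx$image)
  rot <- rotate_image(fx$image, 33)
  vals <- sort(unique(as.vector(rot)))
  expect_true(all(rot %in% 0:255))
  # exact marker colors survive nearest-neighbor resampling
  expect_true(any(rot[, , 1] == 255 & rot[, , 2] == 255 & rot[, , 3] == 0))
})

test_that("rotating +theta then -theta relocates marker pixels within one pixel", {
  # odd dimensions keep the canvas centers aligned on the pixel grid
  img <- gray_canvas(81, 101, 200)
  img <- set_px(img, 20:22, 30:32, c(237, 28, 36))
  img <- set_px(img, 60:62, 70:72, c(34, 177, 76))
  for (theta in c(7, -13, 29)) {
    rt <- rotate_image(rotate_image(img, theta), -theta)
    off_r <- (dim(rt)[1] - dim(img)[1]) / 2
    off_c <- (dim(rt)[2] - dim(img)[2]) / 2
    for (col in list(c(237, 28, 36), c(34, 177, 76))) {
      orig <- which(abs(img[, , 1] - col[1]) + abs(img[, , 2] - col[2]) +
                      abs(img[, , 3] - col[3]) == 0, arr.ind = TRUE)
      back <- which(abs(rt[, , 1] - col[1]) + abs(rt[, , 2] - col[2]) +
                      abs(rt[, , 3] - col[3]) == 0, arr.ind = TRUE)
      expect_gt(nrow(back), 0)
      back <- sweep(back, 2, c(off_r, off_c))
      cheb <- apply(back, 1, function(p) {
        min(pmax(abs(orig[, 1] - p[1]), abs(orig[, 2] - p[2])))
      })
      expect_lte(max(cheb), 1)
    }
  }
})

test_that("crop keeps exactly the interior of the innermost yellow rows and columns", {
  img <- draw_rect(gray_canvas(100, 100), 10, 90, 5, 95)
  cr <- crop_to_roi(img)
  expect_equal(dim(cr)[1:2], c(79, 89))
  expect_equal(unname(attr(cr, "crop_bounds")), c(11, 89, 6, 94))

  # rectangle on the full frame border: interior is the frame minus 1 px
  img2 <- draw_rect(gray_canvas(40, 50), 1, 40, 1, 50)
  cr2 <- crop_to_roi(img2)
  expect_equal(dim(cr2)[1:2], c(38, 48))

  expect_error(crop_to_roi(gray_canvas(20, 20)), class = "missing_roi_error")
  img3 <- draw_rect(gray_canvas(20, 20), 9, 11, 9, 11)
  expect_error(crop_to_roi(img3), class = "malformed_roi_error")
})

test_that("fixture crops match the generator's ROI and are marker-free", {
  for (theta in c(0, -5, 15)) {
    fx <- generate_fixture(fixture_spec(rotation_deg = theta, seed = 4))
    img <- fx$image
    ms <- detect_markers(img)
    rot <- rotate_image(img, compute_rotation_angle(ms))
    cr <- crop_to_roi(rot)
    expect_lte(abs(dim(cr)[1] - fx$truth$roi_height), 2)
    expect_lte(abs(dim(cr)[2] - fx$truth$roi_width), 2)
    for (col in list(c(255, 255, 0), c(237, 28, 36), c(34, 177, 76))) {
      hit <- cr[, , 1] == col[1] & cr[, , 2] == col[2] & cr[, , 3] == col[3]
      expect_false(any(hit))
    }
  }
})

test_that("preprocess on an already-horizontal image crops without altering interior pixels", {
  fx <- generate_fixture(fixture_spec(seed = 5))
  cr <- crop_to_roi(fx$image)  # theta = 0, rotation is the identity
  ct <- fx$truth$content
  expect_equal(dim(cr)[1:2], c(fx$truth$roi_height, fx$truth$roi_width))
  expect_equal(as.vector(cr), as.vector(fx$image[ct$rows, ct$cols, , drop = FALSE]))
})
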