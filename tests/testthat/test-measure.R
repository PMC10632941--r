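# Run-length encoding, column rejection, thickness averaging.

test_that("run-length encoding decomposes columns into maximal runs", {
  b <- matrix(TRUE, 10, 1)
  r <- run_length_encode(b)
  expect_equal(r[[1]], list(bright = TRUE, lengths = 10L))

  b2 <- matrix(c(TRUE, FALSE, TRUE), 3, 1)
  expect_equal(run_length_encode(b2)[[1]],
               list(bright = c(TRUE, FALSE, TRUE), lengths = rep(1L, 3)))

  set.seed(11)
  for (i in 1:100) {
    col <- runif(30) < 0.5
    got <- run_length_encode(matrix(col, ncol = 1))[[1]]
    want <- oracle_rle(col)
    expect_equal(got$bright, want$bright)
    expect_equal(as.integer(got$lengths), want$lengths)
  }
})

test_that("majority first color counts column starts, ties resolving to bright", {
  mk <- function(firsts) {
    run_length_encode(binary_from_runs(lapply(firsts, function(f) {
      list(bright = c(f, !f), lengths = c(3L, 3L))
    })))
  }
  expect_equal(majority_first_color(mk(rep(TRUE, 5))), "bright")
  expect_equal(majority_first_color(mk(c(FALSE, FALSE, FALSE, TRUE, TRUE))), "dark")
  expect_equal(majority_first_color(mk(c(FALSE, FALSE, TRUE, TRUE))), "bright")
})

test_that("columns are rejected by first color or lamella count, never silently", {
  # 5 columns of 2 bright / 1 dark bands, height 9
  clean <- list(bright = c(TRUE, FALSE, TRUE), lengths = c(3L, 3L, 3L))
  minority <- list(bright = c(FALSE, TRUE, FALSE), lengths = c(3L, 3L, 3L))
  split <- list(bright = c(TRUE, FALSE, TRUE, FALSE, TRUE),
                lengths = c(3L, 1L, 1L, 1L, 3L))
  runs <- run_length_encode(binary_from_runs(list(clean, clean, minority, split, clean)))
  mask <- filter_columns(runs, n_bright = 2, n_dark = 1)
  expect_equal(as.logical(mask), c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(attr(mask, "rejected_first_color"), c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(attr(mask, "rejected_count")[4], TRUE)
  expect_error(filter_columns(runs, n_bright = 4, n_dark = 4),
               class = "all_columns_rejected_error")
})

test_that("a single surplus bottom-edge band is ignored when drop_partial_bottom is on", {
  # columns end in a partial dark band beyond the expected 2 bright + 1 dark
  part <- list(bright = c(TRUE, FALSE, TRUE, FALSE), lengths = c(4L, 3L, 4L, 2L))
  runs <- run_length_encode(binary_from_runs(list(part, part)))
  mask_on <- filter_columns(runs, 2, 1, drop_partial_bottom = TRUE)
  expect_true(all(mask_on))
  expect_error(filter_columns(runs, 2, 1, drop_partial_bottom = FALSE),
               class = "all_columns_rejected_error")
  m <- average_thicknesses(runs, mask_on, 2, 1)
  expect_equal(m$avg_bright_um / m$pixel_length_um, c(4, 4))
  expect_equal(m$avg_dark_um / m$pixel_length_um, 3)
})

test_that("averaging takes the positional mean across retained columns in micrometers", {
  a <- list(bright = c(TRUE, FALSE, TRUE), lengths = c(4L, 3L, 5L))
  b <- list(bright = c(TRUE, FALSE, TRUE), lengths = c(6L, 3L, 3L))
  runs <- run_length_encode(binary_from_runs(list(a, b)))
  m <- average_thicknesses(runs, c(TRUE, TRUE), 2, 1)
  expect_equal(m$avg_bright_um, c(5 * 0.3185, 4 * 0.3185))
  expect_equal(m$avg_dark_um, 3 * 0.3185)
  expect_equal(m$n_sets, 2)
  expect_equal(m$ng_sets, 2)
  # a 5-pixel first bright run in every retained column
  five <- list(bright = c(TRUE, FALSE, TRUE), lengths = c(5L, 3L, 4L))
  runs5 <- run_length_encode(binary_from_runs(list(five, five)))
  m5 <- average_thicknesses(runs5, c(TRUE, TRUE), 2, 1)
  expect_equal(m5$avg_bright_um[1], 1.5925)
  # calibration is a config field
  m2 <- average_thicknesses(runs, c(TRUE, TRUE), 2, 1, pixel_length_um = 0.5)
  expect_equal(m2$avg_bright_um, c(2.5, 2))
})

test_that("averaging is invariant to column order and conserves total height", {
  fx <- generate_fixture(fixture_spec(seed = 8))
  bin <- count_assist(fx)
  runs <- run_length_encode(unclass(bin))
  mask <- filter_columns(runs, 4, 3)
  m <- average_thicknesses(runs, mask, 4, 3)
  # conservation: retained columns tile the full crop height
  expect_equal(sum(c(m$avg_bright_um, m$avg_dark_um)) / m$pixel_length_um,
               nrow(bin))
  set.seed(9)
  perm <- sample(ncol(bin))
  runs_p <- run_length_encode(unclass(bin)[, perm])
  m_p <- average_thicknesses(runs_p, mask[perm], 4, 3)
  expect_equal(m_p$avg_bright_um, m$avg_bright_um)
  expect_equal(m_p$avg_dark_um, m$avg_dark_um)
})

test_that("output lengths always equal the expected counts and counts are validated", {
  a <- list(bright = c(FALSE, TRUE, FALSE), lengths = c(2L, 5L, 2L))
  runs <- run_length_encode(binary_from_runs(list(a)))
  m <- average_thicknesses(runs, TRUE, 1, 2)
  expect_length(m$avg_bright_um, 1)
  expect_length(m$avg_dark_um, 2)
  expect_error(filter_columns(runs, 3, 1), class = "invalid_counts_error")
  expect_error(average_thicknesses(runs, TRUE, 0, 1), class = "invalid_counts_error")
})
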