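# Method-agreement utilities: paired percent differences and the exact
# two-sided paired sign test.

#' Paired percent differences
#'
#' Signed percent difference of each automated measurement relative to its
#' manual (reference) counterpart: `100 * (automated - manual) / manual`.
#' Manual measurement is taken as the denominator because it is the gold
#' standard being validated against; the headline mean-absolute figure is
#' sensitive to this choice, so it is fixed and documented here.
#'
#' @param automated,manual Equal-length numeric vectors of positive
#'   thicknesses (micrometers).
#' @return Numeric vector of signed percentages, with attribute
#'   `mean_abs` = mean of their absolute values.
#' @examples
#' d <- percent_differences(c(1.2, 0.8), c(1, 1))
#' attr(d, "mean_abs")  # 20
#' @export
percent_differences <- function(automated, manual) {
  if (length(automated) != length(manual) || length(manual) < 1L) {
    .lamella_stop("invalid_pairs_error",
                  "'automated' and 'manual' must be equal-length vectors of length >= 1")
  }
  if (any(!is.finite(automated)) || any(!is.finite(manual)) ||
      any(automated <= 0) || any(manual <= 0)) {
    .lamella_stop("invalid_pairs_error", "all paired thicknesses must be finite and > 0")
  }
  d <- 100 * (automated - manual) / manual
  attr(d, "mean_abs") <- mean(abs(d))
  d
}

#' Exact two-sided paired sign test
#'
#' Tests whether paired differences are symmetric in sign about zero.
#' Zero differences are discarded (classical convention); with `n` nonzero
#' differences and `k` the smaller of the positive/negative counts, the
#' p-value is the exact doubled binomial tail
#' `min(1, 2 * sum_{j=0..k} choose(n, j) / 2^n)`.
#'
#' @param differences Numeric vector of signed paired differences.
#' @return The exact two-sided p-value.
#' @examples
#' sign_test_two_sided(rep(1, 10))        # 0.001953125
#' sign_test_two_sided(c(rep(1, 3), rep(-1, 7)))  # 0.34375
#' @export
sign_test_two_sided <- function(differences) {
  if (length(differences) < 1L || any(!is.finite(differences))) {
    .lamella_stop("invalid_pairs_error", "'differences' must be a non-empty finite numeric vector")
  }
  d <- differences[differences != 0]
  n <- length(d)
  if (n == 0L) {
    .lamella_stop("degenerate_differences_error",
                  "all differences are zero; the sign test is undefined")
  }
  k <- min(sum(d > 0), sum(d < 0))
  min(1, 2 * stats::pbinom(k, n, 0.5))
}

#' Method-agreement summary
#'
#' Convenience wrapper combining [percent_differences()] and
#' [sign_test_two_sided()] on raw paired differences (automated - manual).
#'
#' @inheritParams percent_differences
#' @return A list with `n`, `percent_differences`, `mean_abs_percent_diff`
#'   and `sign_test_p`.
#' @export
agreement_summary <- function(automated, manual) {
  pd <- percent_differences(automated, manual)
  list(n = length(manual),
       percent_differences = as.numeric(pd),
       mean_abs_percent_diff = attr(pd, "mean_abs"),
       sign_test_p = sign_test_two_sided(automated - manual))
}
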