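# Population-level misclassification projection arithmetic.

#' Annual lung-function tests in a population
#'
#' `round(population x tests_per_10k / 10,000)` with half rounded away
#' from zero (see [round_half_away()]).
#'
#' @param population Persons (non-negative).
#' @param tests_per_10k Tests per 10,000 persons per year (non-negative).
#' @return Whole number of annual tests.
#' @examples
#' annual_tests(35665417, 34.7)  # 123759
#' @export
annual_tests <- function(population, tests_per_10k) {
  check_that("population must be non-negative" = population >= 0,
             "tests_per_10k must be non-negative" = tests_per_10k >= 0)
  round_half_away(population * tests_per_10k / 1e4)
}

#' Projected annual misclassifications
#'
#' `round(tests x error_rate)`, half away from zero.
#'
#' @param tests Annual tests (non-negative).
#' @param error_rate Misclassification rate in `[0, 1]`.
#' @return Whole number of projected misclassified tests.
#' @examples
#' projected_misclassifications(123759, 0.15)  # 18564
#' @export
projected_misclassifications <- function(tests, error_rate) {
  check_that("tests must be non-negative" = tests >= 0,
             "error_rate must be non-negative" = error_rate >= 0,
             "error_rate cannot exceed 1" = error_rate <= 1)
  round_half_away(tests * error_rate)
}

#' Absolute change in prevalence, in percentage points
#'
#' `100 x (n_alternative - n_benchmark) / n_total`: the absolute change
#' in the share of a group called positive when switching from the
#' benchmark to the alternative equation system.
#'
#' @param n_alternative,n_benchmark Positive-call counts under each
#'   system.
#' @param n_total Group size (positive).
#' @return Percentage points (can be negative).
#' @examples
#' prevalence_increase_pct(278, 153, 976)  # ~12.8 percentage points
#' @export
prevalence_increase_pct <- function(n_alternative, n_benchmark, n_total) {
  check_that("counts must be non-negative" = c(n_alternative, n_benchmark) >= 0,
             "n_total must be positive" = n_total > 0)
  100 * (n_alternative - n_benchmark) / n_total
}
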