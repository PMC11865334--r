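# shared small helpers

#' Round half away from zero
#'
#' Nearest-integer rounding with ties broken away from zero, the convention
#' used for all whole-number report figures in this package. Base R's
#' `round()` rounds half to even, which is avoided here so that report
#' numbers are reproducible across platforms and match plain arithmetic.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_away(0.5)   # 1
#' round_half_away(-0.5)  # -1
#' round_half_away(2.345, 2)
#' @export
round_half_away <- function(x, digits = 0) {
  stopifnot(is.numeric(x))
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# z threshold defining the lower/upper limits of normal (5th/95th centile)
LLN_Z <- -1.645

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop unless all named conditions hold; msg built from the first failure
check_that <- function(...) {
  conds <- list(...)
  nms <- names(conds)
  for (i in seq_along(conds)) {
    if (!isTRUE(all(conds[[i]]))) rlang::abort(nms[i])
  }
  invisible(TRUE)
}
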