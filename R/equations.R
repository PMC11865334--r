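# Reference-equation engines.
#
# An equation set is a long tibble (class "spiro_equations") with columns
#   engine, index, sex, population, block, term, value
# holding one or more coefficient tables, each identified by
# (index, sex, population). Two engine kinds are supported:
#
#  * "lms"        — L/M/S coefficient blocks over the closed covariate
#                   vocabulary {intercept, log_height, log_age, age}, plus
#                   optional per-age spline contributions to M and S
#                   (block = "spline", term = "m@<age>" / "s@<age>").
#  * "polynomial" — separate predicted and LLN coefficient blocks over
#                   {intercept, age, age2, height2}.
#
# Units are fixed: age in years, height in cm, volumes in liters, the
# FEV1/FVC ratio dimensionless in (0, 1). Coefficient values themselves are
# user-supplied; no published reference values ship with the package.

LMS_TERMS  <- c("intercept", "log_height", "log_age", "age")
POLY_TERMS <- c("intercept", "age", "age2", "height2")
EQ_INDICES <- c("FEV1", "FVC", "FEV1_FVC")
EQ_SEXES   <- c("male", "female")
EQ_COLS    <- c("engine", "index", "sex", "population", "block", "term", "value")

new_equations <- function(x) {
  structure(dplyr::as_tibble(x), class = c("spiro_equations", class(dplyr::as_tibble(x))))
}

#' Build an LMS coefficient table
#'
#' Constructs the long-format rows for one LMS-engine reference table.
#' The median is \eqn{M = \exp(\sum m_i x_i + M_{spline}(age))}, the
#' coefficient of variation \eqn{S = \exp(\sum s_i x_i + S_{spline}(age))},
#' and the skewness \eqn{L = \sum l_i x_i}, where the covariates \eqn{x_i}
#' are drawn from `intercept`, `log_height` (natural log of height in cm),
#' `log_age` and `age`.
#'
#' @param index One of `"FEV1"`, `"FVC"`, `"FEV1_FVC"`.
#' @param sex `"male"` or `"female"`.
#' @param population Free-text population label (e.g. `"White"`,
#'   `"race-neutral"`).
#' @param m,s,l Named numeric vectors of coefficients; names from the
#'   closed vocabulary `intercept`, `log_height`, `log_age`, `age`.
#' @param spline Optional data frame with columns `age`, `m`, `s` giving
#'   per-age additive contributions (on the log scale) to M and S. Ages
#'   must be strictly increasing.
#' @return A `spiro_equations` tibble.
#' @examples
#' lms_table("FVC", "male", "demo",
#'           m = c(intercept = log(4)), s = c(intercept = log(0.12)),
#'           l = c(intercept = 1))
#' @export
lms_table <- function(index, sex, population, m, s, l, spline = NULL) {
  rows <- dplyr::bind_rows(
    tibble::tibble(block = "m", term = names(m), value = unname(m)),
    tibble::tibble(block = "s", term = names(s), value = unname(s)),
    tibble::tibble(block = "l", term = names(l), value = unname(l))
  )
  if (!is.null(spline)) {
    spline <- dplyr::as_tibble(spline)
    rows <- dplyr::bind_rows(
      rows,
      tibble::tibble(block = "spline", term = paste0("m@", spline$age), value = spline$m),
      tibble::tibble(block = "spline", term = paste0("s@", spline$age), value = spline$s)
    )
  }
  out <- dplyr::mutate(rows, engine = "lms", index = index, sex = sex,
                       population = population, .before = 1)
  validate_equations(new_equations(out))
}

#' Build a polynomial coefficient table
#'
#' Constructs the long-format rows for one polynomial-engine reference
#' table, with separate coefficient sets for the predicted value and for
#' the lower limit of normal (LLN), both linear in the closed vocabulary
#' `intercept`, `age`, `age2` (age squared), `height2` (height squared).
#'
#' @inheritParams lms_table
#' @param predicted,lln Named numeric coefficient vectors.
#' @return A `spiro_equations` tibble.
#' @examples
#' poly_table("FVC", "male", "demo",
#'            predicted = c(intercept = 1, age = 0.01, height2 = 1e-4),
#'            lln = c(intercept = 0.5, age = 0.01, height2 = 1e-4))
#' @export
poly_table <- function(index, sex, population, predicted, lln) {
  out <- dplyr::bind_rows(
    tibble::tibble(block = "predicted", term = names(predicted), value = unname(predicted)),
    tibble::tibble(block = "lln", term = names(lln), value = unname(lln))
  )
  out <- dplyr::mutate(out, engine = "polynomial", index = index, sex = sex,
                       population = population, .before = 1)
  validate_equations(new_equations(out))
}

#' Combine coefficient tables into one equation set
#'
#' @param ... `spiro_equations` tibbles from [lms_table()] / [poly_table()]
#'   (or compatible data frames).
#' @return A validated `spiro_equations` tibble.
#' @export
equation_set <- function(...) {
  validate_equations(new_equations(dplyr::bind_rows(...)))
}

#' Validate an equation set
#'
#' Checks the closed covariate vocabulary, that LMS tables define all of
#' L, M and S, that polynomial tables define both predicted and LLN
#' blocks, and that every spline age grid is strictly increasing.
#'
#' @param eq A `spiro_equations` tibble (or compatible data frame).
#' @return The validated tibble, invisibly classed as `spiro_equations`.
#' @export
validate_equations <- function(eq) {
  eq <- dplyr::as_tibble(eq)
  missing_cols <- setdiff(EQ_COLS, names(eq))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("equation table is missing field(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "spiro_schema_error")
  }
  if (!all(eq$engine %in% c("lms", "polynomial"))) {
    rlang::abort("engine must be 'lms' or 'polynomial'", class = "spiro_schema_error")
  }
  if (!all(eq$index %in% EQ_INDICES)) {
    rlang::abort(paste0("unknown index: ",
                        paste(setdiff(eq$index, EQ_INDICES), collapse = ", ")),
                 class = "spiro_schema_error")
  }
  if (!all(eq$sex %in% EQ_SEXES)) {
    rlang::abort("sex must be 'male' or 'female'", class = "spiro_schema_error")
  }
  if (!is.numeric(eq$value) || anyNA(eq$value)) {
    rlang::abort("value must be numeric and non-missing", class = "spiro_schema_error")
  }
  for (g in split(eq, paste(eq$index, eq$sex, eq$population, sep = "|"))) {
    eng <- unique(g$engine)
    if (length(eng) != 1) {
      rlang::abort("a single table mixes engines", class = "spiro_schema_error")
    }
    if (eng == "lms") {
      non_spline <- g[g$block != "spline", ]
      if (!all(non_spline$block %in% c("m", "s", "l"))) {
        rlang::abort("lms blocks must be m, s, l or spline", class = "spiro_schema_error")
      }
      bad <- setdiff(unique(non_spline$term), LMS_TERMS)
      if (length(bad) > 0) {
        rlang::abort(paste0("unknown lms covariate name(s): ",
                            paste(bad, collapse = ", ")),
                     class = "spiro_schema_error")
      }
      for (b in c("m", "s", "l")) {
        if (!b %in% non_spline$block) {
          rlang::abort(paste0("lms table for ", g$index[1], "/", g$sex[1],
                              "/", g$population[1], " is missing block: ", b),
                       class = "spiro_schema_error")
        }
      }
      sp <- g[g$block == "spline", ]
      if (nrow(sp) > 0) {
        if (!all(grepl("^[ms]@", sp$term))) {
          rlang::abort("spline terms must look like 'm@<age>' or 's@<age>'",
                       class = "spiro_schema_error")
        }
        for (pre in c("m", "s")) {
          ages <- as.numeric(sub("^[ms]@", "",
                                 sp$term[startsWith(sp$term, paste0(pre, "@"))]))
          if (anyNA(ages) || any(duplicated(ages)) ||
              is.unsorted(ages, strictly = TRUE)) {
            rlang::abort("spline age grid must be strictly increasing",
                         class = "spiro_validation_error")
          }
        }
      }
    } else {
      if (!all(g$block %in% c("predicted", "lln"))) {
        rlang::abort("polynomial blocks must be predicted or lln",
                     class = "spiro_schema_error")
      }
      bad <- setdiff(unique(g$term), POLY_TERMS)
      if (length(bad) > 0) {
        rlang::abort(paste0("unknown polynomial covariate name(s): ",
                            paste(bad, collapse = ", ")),
                     class = "spiro_schema_error")
      }
      for (b in c("predicted", "lln")) {
        if (!b %in% g$block) {
          rlang::abort(paste0("polynomial table for ", g$index[1], "/", g$sex[1],
                              "/", g$population[1], " is missing block: ", b),
                       class = "spiro_validation_error")
        }
      }
    }
  }
  new_equations(eq)
}

#' Read / write equation sets
#'
#' Equation sets serialize as tab-separated long format with columns
#' `engine`, `index`, `sex`, `population`, `block`, `term`, `value`.
#' Values are written with enough digits to round-trip exactly.
#'
#' @param path File path.
#' @return `read_equations()` returns a validated `spiro_equations`
#'   tibble; `write_equations()` returns `eq` invisibly.
#' @export
read_equations <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("equation file not found: ", path))
  }
  eq <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          engine = "c", index = "c", sex = "c",
                          population = "c", block = "c", term = "c",
                          value = "d"))
  validate_equations(eq)
}

#' @rdname read_equations
#' @param eq A `spiro_equations` tibble.
#' @export
write_equations <- function(eq, path) {
  eq <- validate_equations(eq)
  out <- dplyr::mutate(eq, value = sprintf("%.17g", .data$value))
  readr::write_tsv(out, path)
  invisible(eq)
}

# select the single table for (index, sex, population); error names the gap
eq_subset <- function(eq, index, sex, population) {
  g <- eq[eq$index == index & eq$sex == sex & eq$population == population, ]
  if (nrow(g) == 0) {
    rlang::abort(paste0("no coefficient table for index=", index,
                        ", sex=", sex, ", population=", population),
                 class = "spiro_config_error")
  }
  g
}

# spline contribution at `age` from rows with prefix "m@"/"s@"; range
# handling (error/clamp) happens in evaluate_lms so ages are in range here
spline_contrib <- function(sp, which, age, interp) {
  rows <- sp[startsWith(sp$term, paste0(which, "@")), ]
  if (nrow(rows) == 0) return(rep(0, length(age)))
  knots <- as.numeric(sub("^[ms]@", "", rows$term))
  o <- order(knots)
  knots <- knots[o]; vals <- rows$value[o]
  if (length(knots) < 3 || interp == "linear") {
    approx(knots, vals, xout = age)$y
  } else {
    splinefun(knots, vals, method = "natural")(age)
  }
}

lms_linear_part <- function(g, block, age, height) {
  b <- g[g$block == block, ]
  co <- setNames(b$value, b$term)
  out <- rep(0, length(age))
  if ("intercept" %in% names(co))  out <- out + co[["intercept"]]
  if ("log_height" %in% names(co)) out <- out + co[["log_height"]] * log(height)
  if ("log_age" %in% names(co))    out <- out + co[["log_age"]] * log(age)
  if ("age" %in% names(co))        out <- out + co[["age"]] * age
  out
}

#' Evaluate an LMS table to (L, M, S)
#'
#' @param eq A `spiro_equations` tibble.
#' @param age Age in years (vectorized).
#' @param height Height in cm (vectorized).
#' @param index,sex,population Table selector.
#' @param interp Spline interpolation between age-grid knots: `"cubic"`
#'   (natural cubic, default) or `"linear"`.
#' @param allow_extrapolation If `TRUE`, ages beyond the spline grid are
#'   clamped to the nearest knot with a warning; otherwise they error.
#' @return A tibble with columns `L`, `M`, `S`.
#' @export
evaluate_lms <- function(eq, age, height, index, sex, population,
                         interp = c("cubic", "linear"),
                         allow_extrapolation = FALSE) {
  interp <- match.arg(interp)
  check_that("age must be positive" = age > 0,
             "height must be positive" = height > 0)
  g <- eq_subset(eq, index, sex, population)
  if (unique(g$engine) != "lms") {
    rlang::abort("selected table is not an lms table")
  }
  sp <- g[g$block == "spline", ]
  spline_age <- age
  if (nrow(sp) > 0) {
    knots <- as.numeric(sub("^[ms]@", "", sp$term))
    lo <- min(knots); hi <- max(knots)
    if (any(age < lo | age > hi)) {
      if (!allow_extrapolation) {
        rlang::abort(paste0("age outside the spline grid [", lo, ", ", hi,
                            "]; set allow_extrapolation = TRUE to clamp"),
                     class = "spiro_range_error")
      }
      rlang::warn("age outside the spline grid; clamped to nearest knot")
      spline_age <- pmin(pmax(age, lo), hi)
    }
  }
  M <- exp(lms_linear_part(g, "m", age, height) +
             spline_contrib(sp, "m", spline_age, interp))
  S <- exp(lms_linear_part(g, "s", age, height) +
             spline_contrib(sp, "s", spline_age, interp))
  L <- lms_linear_part(g, "l", age, height)
  check_that("LMS evaluation produced non-finite values" = is.finite(c(L, M, S)))
  tibble::tibble(L = L, M = M, S = S)
}

#' z-score under the LMS model
#'
#' Computes \eqn{z = ((x/M)^L - 1)/(L S)} for \eqn{|L|} above `1e-6`, and
#' the limit \eqn{z = \log(x/M)/S} as \eqn{L \to 0}. Returns the full
#' result: predicted (median), z, percentile, and lower/upper limits of
#' normal at z = −1.645 / +1.645 (5th/95th centile).
#'
#' @param measured Measured value (liters, or unitless ratio); positive.
#' @param L,M,S LMS parameters; `M`, `S` positive.
#' @return A tibble with columns `predicted`, `L`, `M`, `S`, `z`,
#'   `percentile`, `lln`, `uln`.
#' @examples
#' zscore(3.342, L = 1, M = 4, S = 0.1)  # z = -1.645
#' @export
zscore <- function(measured, L, M, S) {
  check_that("measured must be positive" = measured > 0,
             "M must be positive" = M > 0,
             "S must be positive" = S > 0)
  n <- max(length(measured), length(L), length(M), length(S))
  measured <- rep_len(measured, n); L <- rep_len(L, n)
  M <- rep_len(M, n); S <- rep_len(S, n)
  z <- ifelse(abs(L) > 1e-6,
              ((measured / M)^L - 1) / (L * S),
              log(measured / M) / S)
  tibble::tibble(
    predicted = M, L = L, M = M, S = S, z = z,
    percentile = pnorm(z),
    lln = lms_value_at(LLN_Z, L, M, S),
    uln = lms_value_at(-LLN_Z, L, M, S)
  )
}

#' Value at a given z under the LMS model
#'
#' Inverse of [zscore()]: the measured value whose z-score is `z`.
#'
#' @param z z-score (standard-normal units).
#' @inheritParams zscore
#' @return Numeric vector on the scale of the measurement.
#' @export
lms_value_at <- function(z, L, M, S) {
  check_that("M must be positive" = M > 0, "S must be positive" = S > 0)
  ifelse(abs(L) > 1e-6,
         M * (1 + L * S * z)^(1 / L),
         M * exp(S * z))
}

#' Evaluate a polynomial table to (predicted, LLN)
#'
#' Both the predicted value and the LLN are linear in
#' `{intercept, age, age2, height2}` with separate coefficient sets, the
#' form of US-style polynomial spirometry reference equations. A pseudo
#' z-score for metric interoperability is available via [poly_pseudo_z()].
#'
#' @inheritParams evaluate_lms
#' @return A tibble with columns `predicted`, `lln`, `uln` (the ULN is the
#'   predicted value mirrored about the LLN, an interoperability
#'   convention, not part of the published equation families).
#' @export
evaluate_polynomial <- function(eq, age, height, index, sex, population) {
  g <- eq_subset(eq, index, sex, population)
  if (unique(g$engine) != "polynomial") {
    rlang::abort("selected table is not a polynomial table")
  }
  evalblock <- function(block) {
    b <- g[g$block == block, ]
    co <- setNames(b$value, b$term)
    out <- rep(0, max(length(age), length(height)))
    if ("intercept" %in% names(co)) out <- out + co[["intercept"]]
    if ("age" %in% names(co))       out <- out + co[["age"]] * age
    if ("age2" %in% names(co))      out <- out + co[["age2"]] * age^2
    if ("height2" %in% names(co))   out <- out + co[["height2"]] * height^2
    out
  }
  predicted <- evalblock("predicted")
  lln <- evalblock("lln")
  tibble::tibble(predicted = predicted, lln = lln,
                 uln = predicted + (predicted - lln))
}

#' Pseudo z-score for polynomial-engine tables
#'
#' Maps a measured value to z-score scale so polynomial tables can feed
#' the same classification and metric machinery as LMS tables:
#' \eqn{z = 1.645 (x - predicted)/(predicted - lln)}, so a measurement
#' exactly at the LLN maps to z = −1.645. This is an interoperability
#' convention of this package, not part of the published equations.
#'
#' @param measured Measured value.
#' @param predicted,lln From [evaluate_polynomial()].
#' @return Numeric pseudo z-scores.
#' @export
poly_pseudo_z <- function(measured, predicted, lln) {
  check_that("predicted must exceed lln" = predicted > lln)
  -LLN_Z * (measured - predicted) / (predicted - lln)
}
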