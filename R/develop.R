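# Development of best-fit reference equations from normal-spirometry
# subsets, and the BIC-based test of whether race is a necessary covariate.

COVARIATE_POOL <- c("age", "age2", "age3", "height", "height2", "weight",
                    "sex", "race")

response_column <- function(response) {
  switch(response, FEV1 = "fev1", FVC = "fvc", FEV1_FVC = "ratio",
         rlang::abort(paste0("unknown response: ", response)))
}

# Numeric design matrix (no intercept column) for a covariate subset.
# sex is coded male = 1; race expands to indicator columns with White as
# the reference level when present.
build_design <- function(data, covariates) {
  bad <- setdiff(covariates, COVARIATE_POOL)
  if (length(bad) > 0) {
    rlang::abort(paste0("covariate(s) outside the pool: ",
                        paste(bad, collapse = ", ")))
  }
  cols <- list()
  for (cv in covariates) {
    cols[[cv]] <- switch(cv,
      age = data$age, age2 = data$age^2, age3 = data$age^3,
      height = data$height, height2 = data$height^2,
      weight = data$weight,
      sex = as.numeric(data$sex == "male"),
      race = NULL)
  }
  X <- do.call(cbind, cols[!vapply(cols, is.null, TRUE)])
  if ("race" %in% covariates) {
    races <- factor(data$race,
                    levels = c(intersect("White", unique(data$race)),
                               setdiff(sort(unique(data$race)), "White")))
    lv <- levels(races)
    if (length(lv) < 2) {
      rlang::abort("race covariate requires at least two race labels",
                   class = "spiro_config_error")
    }
    for (r in lv[-1]) {
      rc <- as.numeric(races == r)
      X <- cbind(X, rc)
      colnames(X)[ncol(X)] <- paste0("race", r)
    }
  }
  if (is.null(X)) rlang::abort("no covariates given")
  X
}

#' Select the normal-spirometry development subset
#'
#' Keeps records eligible for reference-equation development: BMI in
#' `[18.5, 34.9]` kg/m2, height in `[142, 206]` cm, weight in `[42, 140]`
#' kg, and all three indices (FEV1, FVC, FEV1/FVC) with z-scores inside
#' `[-1.645, +1.645]` (at or within both limits of normal, inclusive)
#' under the supplied race-neutral equation set.
#'
#' @param data A prepared cohort (see [prepare_records()]).
#' @param equations A `spiro_equations` tibble used race-neutrally.
#' @param population Population label of the race-neutral tables within
#'   `equations` (default `"race-neutral"`).
#' @param bmi_range,height_range,weight_range Closed inclusion brackets.
#' @inheritParams evaluate_lms
#' @return The subset tibble (with z-score columns) carrying an
#'   `exclusions` attribute; see [exclusion_log()].
#' @export
select_normal_subset <- function(data, equations,
                                 population = "race-neutral",
                                 bmi_range = c(18.5, 34.9),
                                 height_range = c(142, 206),
                                 weight_range = c(42, 140),
                                 interp = c("cubic", "linear"),
                                 allow_extrapolation = FALSE) {
  interp <- match.arg(interp)
  z <- add_zscores(data, equations, population = population, interp = interp,
                   allow_extrapolation = allow_extrapolation)
  reason <- dplyr::case_when(
    z$bmi < bmi_range[1] | z$bmi > bmi_range[2] ~ "bmi_out_of_range",
    z$height < height_range[1] | z$height > height_range[2] ~ "height_out_of_range",
    z$weight < weight_range[1] | z$weight > weight_range[2] ~ "weight_out_of_range",
    z$z_fev1 < LLN_Z | z$z_fev1 > -LLN_Z |
      z$z_fvc < LLN_Z | z$z_fvc > -LLN_Z |
      z$z_ratio < LLN_Z | z$z_ratio > -LLN_Z ~ "abnormal_spirometry",
    TRUE ~ NA_character_)
  keep <- is.na(reason)
  if (!any(keep)) {
    rlang::abort(paste0("normal-spirometry subset is empty; review disease ",
                        "prevalence and equation calibration"),
                 class = "spiro_empty_subset")
  }
  out <- z[keep, ]
  attr(out, "exclusions") <- dplyr::count(
    tibble::tibble(reason = reason[!keep]), .data$reason, name = "n")
  attr(out, "n_input") <- nrow(data)
  out
}

#' LASSO covariate screening
#'
#' Standardized LASSO with the penalty chosen by internal 10-fold
#' cross-validation; covariates with nonzero coefficients at the chosen
#' penalty are returned. `race` counts as selected when any of its
#' indicator columns is nonzero. This is a screening step: final
#' coefficients come from the OLS refit ([fit_reference_model()]).
#'
#' @param data Development subset (see [select_normal_subset()]).
#' @param response `"FEV1"`, `"FVC"` or `"FEV1_FVC"`.
#' @param pool Candidate covariates (default the full pool: age, age2,
#'   age3, height, height2, weight, sex, race).
#' @param seed Integer seed; fold assignment and hence the selection are
#'   deterministic given it.
#' @param rule `"min"` (default; penalty minimizing CV error) or `"1se"`.
#' @param nfolds CV folds inside the LASSO (default 10).
#' @return Character vector of selected covariate names, with the chosen
#'   penalty as attribute `lambda`.
#' @export
lasso_select <- function(data, response, pool = COVARIATE_POOL, seed = 1,
                         rule = c("min", "1se"), nfolds = 10) {
  rule <- match.arg(rule)
  y <- data[[response_column(response)]]
  if (nrow(data) < 10 * length(pool)) {
    rlang::abort(paste0("need at least ", 10 * length(pool),
                        " records to screen ", length(pool), " covariates"))
  }
  X <- build_design(data, pool)
  const <- apply(X, 2, function(col) max(col) - min(col) == 0)
  if (any(const)) {
    rlang::warn(paste0("dropping constant covariate column(s): ",
                       paste(colnames(X)[const], collapse = ", ")))
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) < 2) {
    # glmnet needs >= 2 columns; pad with an all-zero dummy that can never
    # be selected
    X <- cbind(X, .dummy = 0)
  }
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(nfolds), nrow(X)))
  cvfit <- glmnet::cv.glmnet(X, y, foldid = foldid, standardize = TRUE)
  lam <- if (rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  beta <- coef(cvfit, s = lam)[-1, 1]
  nz <- names(beta)[beta != 0]
  selected <- unique(ifelse(startsWith(nz, "race"), "race", nz))
  selected <- intersect(pool, selected)  # pool order
  attr(selected, "lambda") <- lam
  selected
}

gaussian_bic <- function(rss, n, k) n * log(rss / n) + k * log(n)

#' Fit a best-fit reference equation by OLS
#'
#' Ordinary least squares of the response on the given covariates (plus
#' intercept). With `trim = TRUE`, records whose externally studentized
#' residual has absolute value >= 3.00 are removed and the model refit,
#' iterated to a fixpoint (at most `max_rounds` rounds). The BIC uses the
#' Gaussian form `n log(RSS/n) + k log(n)`; its additive constant cancels
#' in any between-model difference, which is the only quantity
#' interpreted.
#'
#' @inheritParams lasso_select
#' @param covariates Covariates to fit (subset of the pool; typically
#'   from [lasso_select()]).
#' @param trim Trim gross outliers by studentized residual (default
#'   `TRUE`).
#' @param max_rounds Maximum trimming rounds (default 5).
#' @return A `spiro_fit` object; see [tidy()] and [glance()] methods.
#' @export
fit_reference_model <- function(data, response, covariates, trim = TRUE,
                                max_rounds = 5) {
  ycol <- response_column(response)
  X <- build_design(data, covariates)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    aliased <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X) + 1)] - 1]
    rlang::abort(paste0("rank-deficient design; collinear column(s): ",
                        paste(aliased, collapse = ", ")),
                 class = "spiro_rank_error")
  }
  df <- data.frame(.y = data[[ycol]], X)
  keep <- rep(TRUE, nrow(df))
  n_trimmed <- 0
  for (round in seq_len(if (trim) max_rounds else 1)) {
    fit <- lm(.y ~ ., data = df[keep, , drop = FALSE])
    if (!trim) break
    out <- abs(rstudent(fit)) >= 3.00
    if (!any(out)) break
    idx <- which(keep)[out]
    keep[idx] <- FALSE
    n_trimmed <- n_trimmed + length(idx)
  }
  n <- sum(keep)
  rss <- sum(fit$residuals^2)
  k <- length(coef(fit))
  sm <- summary(fit)
  structure(list(
    model = fit, response = response, covariates = covariates,
    n = n, n_trimmed = n_trimmed, kept = keep,
    r_squared = sm$r.squared, sigma = sm$sigma,
    rss = rss, bic = gaussian_bic(rss, n, k), k = k), class = "spiro_fit")
}

#' @export
print.spiro_fit <- function(x, ...) {
  cat("Best-fit reference equation for", x$response, "\n")
  cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  cat(sprintf("  n = %d (trimmed %d), R^2 = %.4f, residual SD = %.4f L, BIC = %.1f\n",
              x$n, x$n_trimmed, x$r_squared, x$sigma, x$bic))
  invisible(x)
}

#' Tidy a fitted reference equation
#'
#' @param x A `spiro_fit` object.
#' @param ... Unused.
#' @return Tibble of coefficient estimates with standard errors.
#' @method tidy spiro_fit
#' @export
tidy.spiro_fit <- function(x, ...) {
  co <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(co), estimate = co[, 1],
                 std_error = co[, 2], statistic = co[, 3],
                 p_value = co[, 4])
}

#' One-row fit summary
#'
#' @inheritParams tidy.spiro_fit
#' @return Tibble with `n`, `n_trimmed`, `r_squared`, `sigma`, `bic`.
#' @method glance spiro_fit
#' @export
glance.spiro_fit <- function(x, ...) {
  tibble::tibble(response = x$response, n = x$n, n_trimmed = x$n_trimmed,
                 r_squared = x$r_squared, sigma = x$sigma, bic = x$bic,
                 k = x$k)
}

#' Variance-inflation-factor screen with bootstrap CI
#'
#' For each design column, VIF = 1/(1 - R2) from regressing it on the
#' remaining columns; a nonparametric bootstrap over records yields a
#' percentile 95% CI. Columns whose CI upper bound exceeds 10 are flagged
#' for removal, EXCEPT when the collinearity lies within a single
#' variable's polynomial family (age/age2/age3 or height/height2): a
#' column whose VIF drops to 10 or below once its own family members are
#' set aside is exempt.
#'
#' @inheritParams fit_reference_model
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param threshold Removal threshold on the CI upper bound (default 10).
#' @return Tibble with one row per design column: `covariate`, `vif`,
#'   `ci_low`, `ci_high`, `family_exempt`, `remove`.
#' @export
vif_screen <- function(data, covariates, n_boot = 1000, seed = 1,
                       threshold = 10) {
  if (length(covariates) < 2) {
    rlang::abort("vif_screen needs at least 2 covariates")
  }
  X <- build_design(data, covariates)
  fams <- list(age = c("age", "age2", "age3"), height = c("height", "height2"))
  family_of <- function(col) {
    for (f in names(fams)) if (col %in% fams[[f]]) return(f)
    NA_character_
  }
  vif_one <- function(X, j, drop_cols = integer(0)) {
    others <- setdiff(seq_len(ncol(X)), c(j, drop_cols))
    if (length(others) == 0) return(1)
    fit <- stats::lm.fit(cbind(1, X[, others, drop = FALSE]), X[, j])
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  p <- ncol(X)
  point <- vapply(seq_len(p), function(j) vif_one(X, j), 0)
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, p)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(X), nrow(X), replace = TRUE)
    Xb <- X[idx, , drop = FALSE]
    boot[b, ] <- vapply(seq_len(p), function(j) vif_one(Xb, j), 0)
  }
  ci <- apply(boot, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  exempt <- vapply(seq_len(p), function(j) {
    fam <- family_of(colnames(X)[j])
    if (is.na(fam)) return(FALSE)
    mates <- which(colnames(X) %in% setdiff(fams[[fam]], colnames(X)[j]))
    if (length(mates) == 0) return(FALSE)
    vif_one(X, j, drop_cols = mates) <= threshold
  }, TRUE)
  tibble::tibble(
    covariate = colnames(X), vif = point,
    ci_low = ci[1, ], ci_high = ci[2, ],
    family_exempt = exempt,
    remove = !exempt & ci[2, ] > threshold)
}

#' Raftery evidence label for a BIC difference
#'
#' `[0, 2)` weak, `[2, 6)` positive, `[6, 10]` strong, `> 10` very
#' strong evidence for the lower-BIC model.
#'
#' @param delta_bic Non-negative BIC difference.
#' @return Character label.
#' @export
raftery_label <- function(delta_bic) {
  check_that("delta_bic must be non-negative" = delta_bic >= 0)
  dplyr::case_when(delta_bic > 10 ~ "very strong",
                   delta_bic >= 6 ~ "strong",
                   delta_bic >= 2 ~ "positive",
                   TRUE ~ "weak")
}

#' Is race a necessary covariate? (BIC twin-model test)
#'
#' Fits twin OLS models with and without the race covariate on the same
#' records (outlier trimming, when requested, is driven by the with-race
#' model so both twins see identical data) and reports
#' `delta_bic = BIC(without race) - BIC(with race)` on Raftery's evidence
#' scale, together with the share of variance attributable to race
#' (R2 with minus R2 without).
#'
#' @inheritParams fit_reference_model
#' @param covariates Covariates for the with-race model; must include
#'   `"race"`.
#' @return A `spiro_race_test` object with elements `fit_with`,
#'   `fit_without`, `delta_bic`, `evidence`, `favors`, `race_delta_r2`;
#'   see [glance()] method.
#' @export
race_necessity_test <- function(data, response, covariates, trim = TRUE,
                                max_rounds = 5) {
  if (!"race" %in% covariates) {
    rlang::abort("covariates must include 'race'")
  }
  if (length(unique(data$race)) < 2) {
    rlang::abort("race_necessity_test needs at least two race labels",
                 class = "spiro_config_error")
  }
  fit_with <- fit_reference_model(data, response, covariates, trim = trim,
                                  max_rounds = max_rounds)
  twin_data <- data[fit_with$kept, ]
  fit_without <- fit_reference_model(twin_data, response,
                                     setdiff(covariates, "race"),
                                     trim = FALSE)
  delta <- fit_without$bic - fit_with$bic
  structure(list(
    fit_with = fit_with, fit_without = fit_without,
    delta_bic = delta,
    evidence = raftery_label(abs(delta)),
    favors = if (delta >= 0) "include_race" else "exclude_race",
    race_delta_r2 = fit_with$r_squared - fit_without$r_squared),
    class = "spiro_race_test")
}

#' @export
print.spiro_race_test <- function(x, ...) {
  cat("Race-covariate necessity test (", x$fit_with$response, ")\n", sep = "")
  cat(sprintf("  BIC with race %.1f, without %.1f; delta = %.2f\n",
              x$fit_with$bic, x$fit_without$bic, x$delta_bic))
  cat(sprintf("  %s evidence favoring %s; race delta R^2 = %.4f\n",
              x$evidence, gsub("_", " ", x$favors), x$race_delta_r2))
  invisible(x)
}

#' @rdname glance.spiro_fit
#' @method glance spiro_race_test
#' @export
glance.spiro_race_test <- function(x, ...) {
  tibble::tibble(response = x$fit_with$response,
                 n = x$fit_with$n,
                 bic_with_race = x$fit_with$bic,
                 bic_without_race = x$fit_without$bic,
                 delta_bic = x$delta_bic,
                 evidence = x$evidence,
                 favors = x$favors,
                 race_delta_r2 = x$race_delta_r2)
}

#' @rdname tidy.spiro_fit
#' @method tidy spiro_race_test
#' @export
tidy.spiro_race_test <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$fit_with), model = "with_race", .before = 1),
    dplyr::mutate(tidy(x$fit_without), model = "without_race", .before = 1))
}
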