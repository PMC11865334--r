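# Out-of-sample validation: repeated k-fold cross-validation, and
# permutation / bootstrap tests of the RMSE difference between
# race-specific and race-neutral models.

# one random partition into k near-equal folds; guards against folds
# with fewer than 2 records (repartitions, warning)
make_folds <- function(n, k) {
  for (try in 1:100) {
    fold <- sample(rep_len(seq_len(k), n))
    if (min(tabulate(fold, k)) >= 2) return(fold)
    rlang::warn("a fold had fewer than 2 records; repartitioning")
  }
  rlang::abort("could not build folds with >= 2 records each")
}

# mean held-out RMSE and actual-vs-predicted Pearson correlation for one
# model over `repeats` random k-fold partitions. X includes the intercept
# column. Rank-deficient training folds fall back to pivoted coefficients
# with aliased terms set to zero.
cv_engine <- function(X, y, k, repeats, folds = NULL) {
  n <- length(y)
  rmse <- cor_ <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fold <- if (is.null(folds)) make_folds(n, k) else folds[[r]]
    fr <- fc <- numeric(k)
    for (j in seq_len(k)) {
      te <- fold == j
      co <- qr.coef(qr(X[!te, , drop = FALSE]), y[!te])
      co[is.na(co)] <- 0
      pred <- drop(X[te, , drop = FALSE] %*% co)
      fr[j] <- sqrt(mean((y[te] - pred)^2))
      fc[j] <- suppressWarnings(cor(y[te], pred))
    }
    rmse[r] <- mean(fr)
    cor_[r] <- mean(fc, na.rm = TRUE)
  }
  list(rmse = rmse, cor = cor_)
}

#' Repeated k-fold cross-validation of a reference model
#'
#' For each repeat, the data are split into `k` near-equal random folds;
#' the model is fit by OLS on k−1 folds and scored (RMSE and
#' actual-vs-predicted Pearson correlation) on the held-out fold, and
#' fold-level values are averaged per repeat. Deterministic given `seed`.
#'
#' @inheritParams fit_reference_model
#' @param k Number of folds (default 10).
#' @param repeats Number of random re-partitions (default 1000).
#' @param seed Integer seed.
#' @return A `spiro_cv` object; `tidy()` gives per-repeat values,
#'   `glance()` the summaries (median/min/max and central 95% interval of
#'   RMSE; median and 95% interval of the correlation).
#' @export
repeated_cv <- function(data, response, covariates, k = 10, repeats = 1000,
                        seed = 1) {
  y <- data[[response_column(response)]]
  if (length(y) < 2 * k) {
    rlang::abort(paste0("need at least ", 2 * k, " records for ", k, "-fold CV"))
  }
  X <- cbind(1, build_design(data, covariates))
  set.seed(seed)
  res <- cv_engine(X, y, k, repeats)
  structure(list(
    per_repeat = tibble::tibble(repeat_id = seq_len(repeats),
                                rmse = res$rmse, cor = res$cor),
    response = response, covariates = covariates,
    n = length(y), k = k, repeats = repeats, seed = seed),
    class = "spiro_cv")
}

#' @export
print.spiro_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Repeated %d-fold CV (%d repeats) of %s ~ %s\n", x$k, x$repeats,
              x$response, paste(x$covariates, collapse = " + ")))
  cat(sprintf("  RMSE median %.4f L [95%% interval %.4f, %.4f], range [%.4f, %.4f]\n",
              g$rmse_median, g$rmse_ci_low, g$rmse_ci_high, g$rmse_min, g$rmse_max))
  cat(sprintf("  correlation median %.4f [95%% interval %.4f, %.4f]\n",
              g$cor_median, g$cor_ci_low, g$cor_ci_high))
  invisible(x)
}

#' @rdname tidy.spiro_fit
#' @method tidy spiro_cv
#' @export
tidy.spiro_cv <- function(x, ...) x$per_repeat

#' @rdname glance.spiro_fit
#' @method glance spiro_cv
#' @export
glance.spiro_cv <- function(x, ...) {
  r <- x$per_repeat$rmse; cc <- x$per_repeat$cor
  qs <- quantile(r, c(0.025, 0.975), names = FALSE)
  qc <- quantile(cc, c(0.025, 0.975), names = FALSE)
  tibble::tibble(response = x$response, n = x$n, k = x$k, repeats = x$repeats,
                 rmse_median = median(r), rmse_min = min(r), rmse_max = max(r),
                 rmse_ci_low = qs[1], rmse_ci_high = qs[2],
                 cor_median = median(cc), cor_ci_low = qc[1],
                 cor_ci_high = qc[2], seed = x$seed)
}

# CV RMSE/cor difference (race-neutral minus race-specific) with shared
# fold partitions so both models see identical splits
cv_pair_stat <- function(X_with, X_without, y, k, repeats) {
  folds <- replicate(repeats, make_folds(length(y), k), simplify = FALSE)
  a <- cv_engine(X_with, y, k, repeats, folds = folds)
  b <- cv_engine(X_without, y, k, repeats, folds = folds)
  c(rmse_diff = mean(b$rmse) - mean(a$rmse),
    cor_diff = mean(b$cor) - mean(a$cor))
}

race_design_pair <- function(data, response, covariates) {
  if (!"race" %in% covariates) rlang::abort("covariates must include 'race'")
  X_with <- cbind(1, build_design(data, covariates))
  race_cols <- which(startsWith(colnames(X_with), "race"))
  list(y = data[[response_column(response)]],
       X_with = X_with,
       X_without = X_with[, -race_cols, drop = FALSE],
       race_cols = race_cols)
}

new_resampling <- function(method, observed, null_rmse, null_cor, p_rmse,
                           p_cor, n_resamples, seed, extra = list()) {
  structure(c(list(method = method, observed = observed,
                   null_rmse = null_rmse, null_cor = null_cor,
                   p_rmse = p_rmse, p_cor = p_cor,
                   n_resamples = n_resamples, seed = seed), extra),
            class = "spiro_resampling")
}

#' Permutation test of the race term's RMSE contribution
#'
#' Observed statistic: cross-validated RMSE of the race-neutral model
#' minus that of the race-specific model (shared fold partitions, reduced
#' CV repeats). The null distribution is built by permuting the race
#' labels across records — all other covariates stay attached to their
#' records, so exactly the race term's contribution is broken — refitting
#' and recomputing the statistic `n_perm` times. Two-sided
#' p = (1 + #\{|null| >= |observed|\}) / (n_perm + 1).
#'
#' @inheritParams repeated_cv
#' @param covariates Covariates of the race-specific model; must include
#'   `"race"`. The race-neutral twin drops the race indicators.
#' @param n_perm Number of permutations (>= 19; default 199).
#' @param cv_repeats CV repeats per statistic evaluation (default 20;
#'   kept small because the statistic is recomputed for every
#'   permutation).
#' @return A `spiro_resampling` object; see `glance()`.
#' @export
permutation_test_rmse <- function(data, response, covariates, k = 10,
                                  n_perm = 199, cv_repeats = 20, seed = 1) {
  if (n_perm < 19) {
    rlang::abort("n_perm must be >= 19 (p-value resolution too coarse)")
  }
  d <- race_design_pair(data, response, covariates)
  set.seed(seed)
  obs <- cv_pair_stat(d$X_with, d$X_without, d$y, k, cv_repeats)
  n <- length(d$y)
  race_block <- d$X_with[, d$race_cols, drop = FALSE]
  null_rmse <- null_cor <- numeric(n_perm)
  Xp <- d$X_with
  for (i in seq_len(n_perm)) {
    Xp[, d$race_cols] <- race_block[sample.int(n), , drop = FALSE]
    st <- cv_pair_stat(Xp, d$X_without, d$y, k, cv_repeats)
    null_rmse[i] <- st[["rmse_diff"]]
    null_cor[i] <- st[["cor_diff"]]
  }
  p_rmse <- (1 + sum(abs(null_rmse) >= abs(obs[["rmse_diff"]]))) / (n_perm + 1)
  p_cor <- (1 + sum(abs(null_cor) >= abs(obs[["cor_diff"]]))) / (n_perm + 1)
  new_resampling("permutation", obs, null_rmse, null_cor, p_rmse, p_cor,
                 n_perm, seed)
}

#' Bootstrap test of the RMSE difference
#'
#' Resamples records with replacement `n_boot` times; per resample the
#' cross-validated RMSE difference (race-neutral minus race-specific) is
#' recomputed. Reports the percentile 95% CI and a two-sided p-value from
#' the bootstrap distribution's position relative to zero.
#'
#' @inheritParams permutation_test_rmse
#' @param n_boot Number of bootstrap resamples (>= 19; default 199).
#' @param conf_level CI level (default 0.95).
#' @return A `spiro_resampling` object with `ci_low` / `ci_high`.
#' @export
bootstrap_test_rmse <- function(data, response, covariates, k = 10,
                                n_boot = 199, cv_repeats = 20, seed = 1,
                                conf_level = 0.95) {
  if (n_boot < 19) {
    rlang::abort("n_boot must be >= 19 (resolution too coarse)")
  }
  d <- race_design_pair(data, response, covariates)
  set.seed(seed)
  obs <- cv_pair_stat(d$X_with, d$X_without, d$y, k, cv_repeats)
  n <- length(d$y)
  boot_rmse <- boot_cor <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    st <- cv_pair_stat(d$X_with[idx, , drop = FALSE],
                       d$X_without[idx, , drop = FALSE], d$y[idx], k,
                       cv_repeats)
    boot_rmse[i] <- st[["rmse_diff"]]
    boot_cor[i] <- st[["cor_diff"]]
  }
  alpha <- 1 - conf_level
  ci <- quantile(boot_rmse, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  two_sided_p <- function(bs) {
    min(1, 2 * min((1 + sum(bs <= 0)) / (n_boot + 1),
                   (1 + sum(bs >= 0)) / (n_boot + 1)))
  }
  new_resampling("bootstrap", obs, boot_rmse, boot_cor,
                 two_sided_p(boot_rmse), two_sided_p(boot_cor),
                 n_boot, seed,
                 extra = list(ci_low = ci[1], ci_high = ci[2],
                              conf_level = conf_level))
}

#' @export
print.spiro_resampling <- function(x, ...) {
  cat(sprintf("%s test of the CV-RMSE difference (race-neutral - race-specific)\n",
              x$method))
  cat(sprintf("  observed RMSE difference %.4f L, p = %.4g (%d resamples)\n",
              x$observed[["rmse_diff"]], x$p_rmse, x$n_resamples))
  if (!is.null(x$ci_low)) {
    cat(sprintf("  %.0f%% percentile CI [%.4f, %.4f]\n",
                100 * x$conf_level, x$ci_low, x$ci_high))
  }
  cat(sprintf("  observed correlation difference %.4f, p = %.4g\n",
              x$observed[["cor_diff"]], x$p_cor))
  invisible(x)
}

#' @rdname glance.spiro_fit
#' @method glance spiro_resampling
#' @export
glance.spiro_resampling <- function(x, ...) {
  tibble::tibble(method = x$method,
                 rmse_diff = x$observed[["rmse_diff"]],
                 cor_diff = x$observed[["cor_diff"]],
                 p_rmse = x$p_rmse, p_cor = x$p_cor,
                 ci_low = x$ci_low %||% NA_real_,
                 ci_high = x$ci_high %||% NA_real_,
                 n_resamples = x$n_resamples, seed = x$seed)
}
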