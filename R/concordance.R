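# Agreement between two classification runs: Cohen's kappa, the 1 - kappa
# discordance categories, and the confusion-matrix metric suite, with the
# race-specific (benchmark) call playing the role of truth.

#' Cohen's kappa for paired binary labels
#'
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with observed agreement \eqn{p_o}
#' and chance agreement \eqn{p_e} from the two raters' marginals. The 95%
#' confidence interval uses the large-sample standard error
#' \eqn{\sqrt{p_o(1-p_o)/(n(1-p_e)^2)}} by default; a nonparametric
#' bootstrap over pairs is available.
#'
#' @param benchmark,alternative Logical (or two-level) label vectors of
#'   equal length, at least 2 pairs.
#' @param conf_level Confidence level (default 0.95).
#' @param method `"asymptotic"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap resamples when `method = "bootstrap"`.
#' @return A one-row tibble: `kappa`, `ci_low`, `ci_high`, `n`, `p_o`,
#'   `p_e`.
#' @examples
#' b <- rep(c(TRUE, FALSE), c(50, 50))
#' a <- rep(c(TRUE, FALSE, TRUE, FALSE), c(45, 5, 5, 45))
#' cohen_kappa(b, a)  # kappa = 0.8
#' @export
cohen_kappa <- function(benchmark, alternative, conf_level = 0.95,
                        method = c("asymptotic", "bootstrap"),
                        n_boot = 1000) {
  method <- match.arg(method)
  x <- as.logical(benchmark); y <- as.logical(alternative)
  check_that("labels must have equal length" = length(x) == length(y),
             "need at least 2 pairs" = length(x) >= 2,
             "labels must be non-missing" = !is.na(c(x, y)))
  n <- length(x)
  kap <- function(x, y) {
    po <- mean(x == y)
    pe <- mean(x) * mean(y) + mean(!x) * mean(!y)
    if (pe >= 1 - 1e-12) {
      rlang::abort("kappa undefined: both raters are constant (chance agreement = 1)",
                   class = "spiro_kappa_undefined")
    }
    (po - pe) / (1 - pe)
  }
  po <- mean(x == y)
  pe <- mean(x) * mean(y) + mean(!x) * mean(!y)
  k <- kap(x, y)
  alpha <- 1 - conf_level
  if (method == "asymptotic") {
    se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
    zq <- qnorm(1 - alpha / 2)
    lo <- max(-1, k - zq * se); hi <- min(1, k + zq * se)
  } else {
    ks <- purrr::map_dbl(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(kap(x[idx], y[idx]), error = function(e) NA_real_)
    })
    qs <- quantile(ks, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE, names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  tibble::tibble(kappa = k, ci_low = lo, ci_high = hi, n = n, p_o = po, p_e = pe)
}

#' Discordance category from 1 - kappa
#'
#' Bins the discordance (1 − κ) into the qualitative scheme
#' `[0, 0.1)` negligible, `[0.1, 0.2)` very low, `[0.2, 0.4)` low,
#' `[0.4, 0.6)` moderate, `[0.6, 0.8)` high, `[0.8, ∞)` very high. The
#' published scheme leaves small gaps between bins (e.g. 0.2 to 0.21);
#' they are closed here as contiguous half-open intervals.
#'
#' @param one_minus_kappa Numeric in `[0, 2]`.
#' @return Character vector of category labels.
#' @examples
#' discordance_category(c(0, 0.14, 0.21))
#' @export
discordance_category <- function(one_minus_kappa) {
  check_that("discordance must be non-negative" = one_minus_kappa >= 0,
             "discordance cannot exceed 2" = one_minus_kappa <= 2)
  # snap to 10 decimals so float noise (e.g. 1 - 0.8 = 0.19999...) cannot
  # push a value across a bin edge
  x <- round(one_minus_kappa, 10)
  labs <- c("negligible", "very low", "low", "moderate", "high", "very high")
  as.character(cut(x, breaks = c(0, 0.1, 0.2, 0.4, 0.6, 0.8, Inf),
                   labels = labs, right = FALSE))
}

#' Classification-accuracy category from the MCC
#'
#' `> 0.80` robust, `0.60–0.80` moderately strong, `0.50–0.60`
#' fair–moderate (a band the published scheme leaves unassigned),
#' `0.30–0.50` fair, `< 0.30` poor.
#'
#' @param mcc Numeric in `[-1, 1]`.
#' @return Character vector of category labels.
#' @export
mcc_category <- function(mcc) {
  check_that("mcc must be in [-1, 1]" = mcc >= -1 - 1e-12 & mcc <= 1 + 1e-12)
  mcc <- round(mcc, 10)
  dplyr::case_when(
    mcc > 0.8 ~ "robust",
    mcc >= 0.6 ~ "moderately strong",
    mcc >= 0.5 ~ "fair-moderate",
    mcc >= 0.3 ~ "fair",
    TRUE ~ "poor")
}

#' 2x2 confusion counts with the benchmark as truth
#'
#' @param benchmark,alternative Logical vectors; the benchmark
#'   (race-specific) call is treated as truth.
#' @return A one-row tibble with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(benchmark, alternative) {
  b <- as.logical(benchmark); a <- as.logical(alternative)
  check_that("labels must have equal length" = length(b) == length(a),
             "labels must be non-missing" = !is.na(c(b, a)))
  tibble::tibble(tp = sum(b & a), fp = sum(!b & a),
                 fn = sum(b & !a), tn = sum(!b & !a))
}

# rank-statistic AUC (Mann-Whitney) of scores against binary labels
rank_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Confusion-matrix metric suite
#'
#' Computes the full metric suite from a 2x2 table: TPR, TNR, PPV, NPV
#' and their complements FNR, FPR, FDR (= FP/(FP+TP)), FOR (= FN/(FN+TN)),
#' the Matthews correlation coefficient
#' \eqn{(tp\,tn - fp\,fn)/\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}}, the F1
#' score, and (when continuous scores are supplied) the rank-statistic
#' AUC against the benchmark labels. A metric with a zero denominator is
#' reported as `NA`, and its identity partner (e.g. FDR for PPV) is
#' suppressed likewise.
#'
#' @param confusion A one-row tibble/data frame with `tp`, `fp`, `fn`,
#'   `tn` (see [confusion_counts()]).
#' @param scores Optional continuous scores (one per paired record, in
#'   benchmark-then-order used to build the confusion table is not
#'   needed; supply alongside `benchmark` labels).
#' @param benchmark Optional logical labels matching `scores`.
#' @return A one-row tibble of metrics plus `mcc_category`.
#' @export
metric_suite <- function(confusion, scores = NULL, benchmark = NULL) {
  # doubles: the MCC denominator product overflows 32-bit integers
  tp <- as.numeric(confusion$tp); fp <- as.numeric(confusion$fp)
  fn <- as.numeric(confusion$fn); tn <- as.numeric(confusion$tn)
  check_that("counts must be non-negative" = c(tp, fp, fn, tn) >= 0,
             "table total must be positive" = tp + fp + fn + tn > 0)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  tpr <- rate(tp, tp + fn); tnr <- rate(tn, tn + fp)
  ppv <- rate(tp, tp + fp); npv <- rate(tn, tn + fn)
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 > 0) (tp * tn - fp * fn) / sqrt(denom2) else NA_real_
  f1 <- if (!is.na(ppv) && !is.na(tpr) && (ppv + tpr) > 0)
    2 * ppv * tpr / (ppv + tpr) else NA_real_
  auc <- if (!is.null(scores)) rank_auc(scores, as.logical(benchmark)) else NA_real_
  tibble::tibble(
    tpr = tpr, tnr = tnr, ppv = ppv, npv = npv,
    fnr = if (is.na(tpr)) NA_real_ else 1 - tpr,
    fpr = if (is.na(tnr)) NA_real_ else 1 - tnr,
    fdr = if (is.na(ppv)) NA_real_ else 1 - ppv,
    for_ = if (is.na(npv)) NA_real_ else 1 - npv,
    mcc = mcc, f1 = f1, auc = auc,
    mcc_category = if (is.na(mcc)) NA_character_ else mcc_category(mcc))
}

#' Full paired comparison of two classification runs
#'
#' Rolls paired binary calls (benchmark = race-specific, alternative =
#' race-neutral or any second equation system) into one report row:
#' discordant count and whole-percent share of all paired records, Cohen's
#' kappa with CI, the 1 − κ discordance category, and the metric suite.
#'
#' @inheritParams cohen_kappa
#' @param scores Optional continuous scores for the AUC (typically the
#'   alternative run's z-score for the pattern-defining index).
#' @return A one-row tibble.
#' @export
compare_classifications <- function(benchmark, alternative, scores = NULL,
                                    conf_level = 0.95,
                                    method = c("asymptotic", "bootstrap")) {
  b <- as.logical(benchmark); a <- as.logical(alternative)
  kp <- cohen_kappa(b, a, conf_level = conf_level, method = method)
  cm <- confusion_counts(b, a)
  ms <- metric_suite(cm, scores = scores, benchmark = b)
  disc <- sum(b != a)
  one_minus_kappa <- 1 - kp$kappa
  dplyr::bind_cols(
    tibble::tibble(
      n = kp$n,
      positive_benchmark_pct = round_half_away(100 * mean(b)),
      discordant_n = disc,
      discordant_pct = round_half_away(100 * disc / kp$n),
      kappa = kp$kappa, kappa_ci_low = kp$ci_low, kappa_ci_high = kp$ci_high,
      one_minus_kappa = one_minus_kappa,
      discordance_category = discordance_category(max(0, one_minus_kappa))),
    cm, ms)
}
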