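# Synthetic cohort generation.
#
# The generator emulates the demographic strata of a large single-center
# adult clinical spirometry population (per race x sex means, SDs and
# ranges of age, height and weight), with FVC produced from a latent
# linear truth model plus Gaussian noise, FEV1 as a drawn FEV1/FVC ratio
# times FVC, race offsets expressed as height-linear differences from the
# White baseline, and configurable injection of obstructive/restrictive
# disease. Every latent value is logged so downstream modules can be
# tested against known truth.

#' Default demographic strata
#'
#' Six race-by-sex strata with counts, age/height/weight means, SDs and
#' ranges matching the normal-spirometry development population of the
#' clinical dataset the generator emulates.
#'
#' @return A tibble, one row per stratum.
#' @export
default_strata <- function() {
  tibble::tribble(
    ~race, ~sex, ~n,
    ~age_mean, ~age_sd, ~age_min, ~age_max,
    ~height_mean, ~height_sd, ~height_min, ~height_max,
    ~weight_mean, ~weight_sd, ~weight_min, ~weight_max,
    "White",    "male",   1108, 60, 18, 18, 95, 178, 8, 149, 206, 87.3, 14.2, 43, 130,
    "Black",    "male",    136, 55, 17, 18, 92, 178, 8, 157, 203, 89.4, 13.3, 52, 140,
    "Hispanic", "male",    457, 52, 17, 18, 90, 170, 8, 150, 193, 81.5, 13.4, 48, 122,
    "White",    "female", 1352, 58, 18, 18, 95, 163, 7, 142, 189, 71.6, 13.0, 42, 121,
    "Black",    "female",  231, 56, 17, 18, 90, 163, 6, 145, 188, 74.0, 12.5, 47, 108,
    "Hispanic", "female",  487, 50, 18, 18, 92, 158, 7, 142, 180, 68.7, 11.9, 42, 109
  )
}

#' Default truth model
#'
#' The latent data-generating model: FVC mean linear in
#' \{age, height^2, male\}, Gaussian residual SD 0.40 L; the FEV1/FVC
#' ratio drawn from a truncated normal whose mean declines 0.002/year
#' after age 40; race offsets (subtracted from the White baseline) linear
#' in height: Black FVC +0.40 L at 140 cm to +0.70 L at 185 cm, Black
#' FEV1 +0.27 to +0.48 L over the same span, Hispanic FEV1 a constant
#' +0.56 L, Hispanic FVC +0.25 L at 140 cm shrinking to 0 at 175 cm (all
#' favoring Whites). Disease injection defaults: 17% obstruction
#' prevalence with FEV1 shrink factors U(0.5, 0.9), 17% restriction
#' prevalence with proportional FVC/FEV1 shrinkage from the same range —
#' factors chosen to straddle the lower limit of normal so classification
#' machinery sees boundary cases.
#'
#' @param race_offset_scale Multiplier on all race offsets (0 switches
#'   race effects off).
#' @param sigma Residual SD of FVC in liters (default 0.40).
#' @param obstruction_prevalence,restriction_prevalence Injection rates
#'   for [inject_disease()].
#' @return A list understood by [generate_cohort()].
#' @export
default_truth <- function(race_offset_scale = 1, sigma = 0.40,
                          obstruction_prevalence = 0.17,
                          restriction_prevalence = 0.17) {
  list(
    fvc = c(intercept = -2.41, age = -0.02, height2 = 0.00025, sex = 0.10),
    sigma = sigma,
    ratio_mean = 0.82, ratio_sd = 0.05,
    ratio_age_decline = 0.002, ratio_decline_onset = 40,
    ratio_range = c(0.18, 0.95),
    # value at 140 cm, value at 185 cm; zero_above: height at which the
    # offset has shrunk to zero (NA = plain linear over 140..185)
    offsets = tibble::tribble(
      ~race, ~index, ~at140, ~at185, ~zero_above,
      "Black",    "FVC",  0.40, 0.70, NA,
      "Black",    "FEV1", 0.27, 0.48, NA,
      "Hispanic", "FEV1", 0.56, 0.56, NA,
      "Hispanic", "FVC",  0.25, NA,   175
    ),
    race_offset_scale = race_offset_scale,
    obstruction_prevalence = obstruction_prevalence,
    restriction_prevalence = restriction_prevalence,
    obstruction_shrink = c(0.5, 0.9),
    restriction_shrink = c(0.5, 0.9)
  )
}

#' Race offset at given heights
#'
#' The height-dependent difference (liters) subtracted from the White
#' baseline for a race and index under a truth model.
#'
#' @param truth Truth model from [default_truth()].
#' @param race,index Selector (`"White"` returns 0).
#' @param height Heights in cm (vectorized).
#' @return Numeric offsets in liters.
#' @export
race_offset <- function(truth, race, index, height) {
  if (race == "White") return(rep(0, length(height)))
  row <- truth$offsets[truth$offsets$race == race & truth$offsets$index == index, ]
  if (nrow(row) == 0) return(rep(0, length(height)))
  off <- if (!is.na(row$zero_above)) {
    pmax(0, row$at140 * (1 - (height - 140) / (row$zero_above - 140)))
  } else {
    row$at140 + (row$at185 - row$at140) * (height - 140) / 45
  }
  truth$race_offset_scale * off
}

# range-truncated normal by rejection sampling (resample cap per stratum)
rtrunc_norm <- function(n, mean, sd, lo, hi, cap = 1e5) {
  if (lo > mean + 5 * sd || hi < mean - 5 * sd) {
    rlang::abort(paste0("infeasible truncation: range [", lo, ", ", hi,
                        "] excludes mean +/- 5 SD"),
                 class = "spiro_config_error")
  }
  if (n == 0) return(numeric(0))
  out <- numeric(0)
  drawn <- 0
  while (length(out) < n && drawn < cap) {
    x <- rnorm(n * 2, mean, sd)
    drawn <- drawn + length(x)
    out <- c(out, x[x >= lo & x <= hi])
  }
  if (length(out) < n) rlang::abort("truncated-normal rejection cap exceeded")
  out[seq_len(n)]
}

ratio_mean_at <- function(truth, age) {
  truth$ratio_mean - truth$ratio_age_decline *
    pmax(age - truth$ratio_decline_onset, 0)
}

fvc_truth_mean <- function(truth, age, height, sex) {
  co <- truth$fvc
  co[["intercept"]] + co[["age"]] * age + co[["height2"]] * height^2 +
    co[["sex"]] * as.numeric(sex == "male")
}

#' Generate a synthetic spirometry cohort
#'
#' Draws demographics from range-truncated normals per stratum, FVC from
#' the truth model plus Gaussian noise, the FEV1/FVC ratio from its own
#' truncated normal, FEV1 = ratio x FVC, then applies the race offsets.
#' FEV1 is finally capped at 0.95 x FVC so every record satisfies
#' fev1 < fvc with a physiological ratio. All latent values are recorded
#' in the `truth_log` attribute, retrievable with [truth_log()].
#'
#' @param strata Stratum table (see [default_strata()]).
#' @param truth Truth model (see [default_truth()]).
#' @param seed Integer seed; the cohort is deterministic given it.
#' @return A record tibble with the standard cohort columns (`svc` is all
#'   `NA`; `visit` is 1) and attribute `truth_log`.
#' @export
generate_cohort <- function(strata = default_strata(),
                            truth = default_truth(), seed = 1) {
  set.seed(seed)
  rows <- purrr::pmap(strata, function(race, sex, n, age_mean, age_sd,
                                       age_min, age_max, height_mean,
                                       height_sd, height_min, height_max,
                                       weight_mean, weight_sd, weight_min,
                                       weight_max) {
    age <- rtrunc_norm(n, age_mean, age_sd, max(18, age_min), age_max)
    height <- rtrunc_norm(n, height_mean, height_sd, height_min, height_max)
    weight <- rtrunc_norm(n, weight_mean, weight_sd, weight_min, weight_max)
    tibble::tibble(race = race, sex = sex, age = age, height = height,
                   weight = weight)
  })
  d <- dplyr::bind_rows(rows)
  n <- nrow(d)
  if (n == 0) {
    d <- tibble::tibble(id = character(), race = character(), sex = character(),
                        age = numeric(), height = numeric(), weight = numeric(),
                        bmi = numeric(), fev1 = numeric(), fvc = numeric(),
                        svc = numeric(), visit = integer(), ratio = numeric())
    attr(d, "truth_log") <- d[0, 0]
    return(d)
  }
  mean_fvc <- fvc_truth_mean(truth, d$age, d$height, d$sex)
  noise <- rnorm(n, 0, truth$sigma)
  base_fvc <- mean_fvc + noise
  ratio <- rtrunc_norm_vec(ratio_mean_at(truth, d$age), truth$ratio_sd,
                           truth$ratio_range[1], truth$ratio_range[2])
  base_fev1 <- ratio * base_fvc
  off_fvc <- off_fev1 <- numeric(n)
  for (r in unique(d$race)) {
    i <- d$race == r
    off_fvc[i] <- race_offset(truth, r, "FVC", d$height[i])
    off_fev1[i] <- race_offset(truth, r, "FEV1", d$height[i])
  }
  fvc <- pmax(base_fvc - off_fvc, 0.5)
  fev1 <- pmin(base_fev1 - off_fev1, 0.95 * fvc)
  fev1 <- pmax(fev1, truth$ratio_range[1] * fvc)
  out <- tibble::tibble(
    id = sprintf("S%05d", seq_len(n)),
    race = d$race, sex = d$sex, age = d$age, height = d$height,
    weight = d$weight, bmi = d$weight / (d$height / 100)^2,
    fev1 = fev1, fvc = fvc, svc = NA_real_, visit = 1L,
    ratio = fev1 / fvc)
  attr(out, "truth_log") <- tibble::tibble(
    id = out$id, mean_fvc = mean_fvc, noise = noise, base_fvc = base_fvc,
    ratio_latent = ratio, offset_fvc = off_fvc, offset_fev1 = off_fev1)
  out
}

# elementwise-mean truncated normal (shared sd and range)
rtrunc_norm_vec <- function(means, sd, lo, hi, cap = 100) {
  out <- rnorm(length(means), means, sd)
  for (i in seq_len(cap)) {
    bad <- out < lo | out > hi
    if (!any(bad)) return(out)
    out[bad] <- rnorm(sum(bad), means[bad], sd)
  }
  pmin(pmax(out, lo), hi)
}

#' Access the truth log of a generated cohort
#'
#' @param x A tibble from [generate_cohort()] or [inject_disease()].
#' @return The latent-value tibble recorded at generation time.
#' @export
truth_log <- function(x) attr(x, "truth_log")

#' Inject obstructive and restrictive disease
#'
#' Randomly designates records as obstructed (FEV1 multiplied by a draw
#' from the obstruction shrink range, so the ratio falls) or restricted
#' (FVC and FEV1 both multiplied by a draw from the restriction shrink
#' range, so the ratio is preserved while FVC falls). True labels are
#' returned in the `true_pattern` column for classifier oracle tests.
#'
#' @param cohort A tibble from [generate_cohort()].
#' @param truth Truth model carrying the prevalences and shrink ranges.
#' @param seed Integer seed.
#' @return The modified cohort with a `true_pattern` column.
#' @export
inject_disease <- function(cohort, truth = default_truth(), seed = 1) {
  p_o <- truth$obstruction_prevalence
  p_r <- truth$restriction_prevalence
  if (p_o + p_r > 1) {
    rlang::abort("obstruction + restriction prevalence exceeds 1",
                 class = "spiro_config_error")
  }
  set.seed(seed)
  n <- nrow(cohort)
  u <- runif(n)
  lab <- dplyr::case_when(u < p_o ~ "obstruction",
                          u < p_o + p_r ~ "restrictive",
                          TRUE ~ "normal")
  obs <- lab == "obstruction"
  res <- lab == "restrictive"
  f_o <- runif(sum(obs), truth$obstruction_shrink[1], truth$obstruction_shrink[2])
  f_r <- runif(sum(res), truth$restriction_shrink[1], truth$restriction_shrink[2])
  cohort$fev1[obs] <- cohort$fev1[obs] * f_o
  cohort$fvc[res] <- cohort$fvc[res] * f_r
  cohort$fev1[res] <- cohort$fev1[res] * f_r
  cohort$ratio <- cohort$fev1 / cohort$fvc
  cohort$true_pattern <- lab
  cohort
}

#' Derive calibrated synthetic equation sets from a truth model
#'
#' Projects the generator's truth mean functions onto the
#' polynomial-engine vocabulary \{intercept, age, age2, height2\} on a
#' deterministic demographic grid, yielding coefficient tables per sex
#' per index — per population when `race_specific = TRUE` (labels =
#' race names), or pooled with stratum-size weights into a single
#' `"race-neutral"` population otherwise. The LLN sits 1.645 effective
#' SDs below the predicted value, where the effective SD combines the
#' truth residual SD (plus ratio-variance propagation for FEV1) with the
#' projection error. These are synthetic calibration tables, not
#' published reference values.
#'
#' @inheritParams generate_cohort
#' @param race_specific Build per-race tables (`TRUE`) or one pooled
#'   race-neutral set (`FALSE`).
#' @return A `spiro_equations` tibble.
#' @export
derive_equation_set <- function(truth = default_truth(),
                                strata = default_strata(),
                                race_specific = TRUE) {
  strata <- strata[strata$n > 0, ]
  if (nrow(strata) == 0) rlang::abort("all strata are empty")
  grids <- purrr::pmap(strata, function(race, sex, n, age_mean, age_sd,
                                        age_min, age_max, height_mean,
                                        height_sd, height_min, height_max,
                                        ...) {
    g <- tidyr::expand_grid(
      age = seq(max(18, age_min), age_max, length.out = 12),
      height = seq(max(height_min, height_mean - 2 * height_sd),
                   min(height_max, height_mean + 2 * height_sd),
                   length.out = 10))
    dplyr::mutate(g, race = race, sex = sex, w = n)
  })
  grid <- dplyr::bind_rows(grids)
  grid$mu_fvc_base <- fvc_truth_mean(truth, grid$age, grid$height, grid$sex)
  grid$rbar <- ratio_mean_at(truth, grid$age)
  off_fvc <- off_fev1 <- numeric(nrow(grid))
  for (r in unique(grid$race)) {
    i <- grid$race == r
    off_fvc[i] <- race_offset(truth, r, "FVC", grid$height[i])
    off_fev1[i] <- race_offset(truth, r, "FEV1", grid$height[i])
  }
  grid$mu_fvc <- grid$mu_fvc_base - off_fvc
  grid$mu_fev1 <- grid$rbar * grid$mu_fvc_base - off_fev1
  grid$sd_fvc <- truth$sigma
  grid$sd_fev1 <- sqrt((grid$rbar * truth$sigma)^2 +
                         (truth$ratio_sd * grid$mu_fvc_base)^2)
  # the per-index offsets shift the realized ratio too: at equal
  # covariates the ratio mean is (rbar*mu - off_fev1)/(mu - off_fvc)
  grid$mu_ratio <- grid$mu_fev1 / grid$mu_fvc
  grid$sd_ratio <- truth$ratio_sd * grid$mu_fvc_base / grid$mu_fvc

  project_block <- function(g, mu, sd) {
    X <- cbind(intercept = 1, age = g$age, age2 = g$age^2,
               height2 = g$height^2)
    co <- qr.coef(qr(X * sqrt(g$w)), mu * sqrt(g$w))
    co[is.na(co)] <- 0
    resid_sd <- sqrt(sum(g$w * (mu - drop(X %*% co))^2) / sum(g$w))
    sd_eff <- sqrt(mean(sd)^2 + resid_sd^2)
    lln_vals <- mu - 1.645 * sd
    co_lln <- qr.coef(qr(X * sqrt(g$w)), lln_vals * sqrt(g$w))
    co_lln[is.na(co_lln)] <- 0
    # widen the LLN by the projection error so the table stays calibrated
    co_lln[["intercept"]] <- co_lln[["intercept"]] - 1.645 * (sd_eff - mean(sd))
    list(predicted = co, lln = co_lln)
  }

  specs <- if (race_specific) {
    dplyr::distinct(grid, .data$race, .data$sex)
  } else {
    dplyr::distinct(grid, .data$sex)
  }
  tabs <- purrr::pmap(specs, function(sex, race = NULL) {
    g <- if (is.null(race)) grid[grid$sex == sex, ]
         else grid[grid$sex == sex & grid$race == race, ]
    pop <- if (is.null(race)) "race-neutral" else race
    purrr::map(c(FEV1 = "FEV1", FVC = "FVC", FEV1_FVC = "FEV1_FVC"),
      function(index) {
        mu <- switch(index, FEV1 = g$mu_fev1, FVC = g$mu_fvc,
                     FEV1_FVC = g$mu_ratio)
        sd <- switch(index, FEV1 = g$sd_fev1, FVC = g$sd_fvc,
                     FEV1_FVC = g$sd_ratio)
        pb <- project_block(g, mu, sd)
        poly_table(index, sex, pop, predicted = pb$predicted, lln = pb$lln)
      }) |> dplyr::bind_rows()
  })
  equation_set(dplyr::bind_rows(tabs))
}
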