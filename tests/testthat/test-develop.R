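test_that("normal-subset selection applies the development brackets", {
  eq <- derive_equation_set(race_specific = FALSE)
  co <- inject_disease(generate_cohort(small_strata(300, 100), seed = 31),
                       seed = 32)
  sub <- select_normal_subset(co, eq)
  expect_true(all(sub$bmi >= 18.5 & sub$bmi <= 34.9))
  expect_true(all(sub$height >= 142 & sub$height <= 206))
  expect_true(all(sub$weight >= 42 & sub$weight <= 140))
  expect_true(all(abs(sub$z_fev1) <= 1.645 & abs(sub$z_fvc) <= 1.645 &
                    abs(sub$z_ratio) <= 1.645))
  log <- exclusion_log(sub)
  expect_equal(sum(log$n) + nrow(sub), nrow(co))

  # boundary: BMI 35.0 is outside the closed bracket
  n_bmi <- function(x) {
    lg <- exclusion_log(x)
    sum(lg$n[lg$reason == "bmi_out_of_range"])
  }
  probe <- co[1, ]
  probe$weight <- 35.0 * (probe$height / 100)^2
  probe$bmi <- 35.0
  expect_equal(n_bmi(select_normal_subset(rbind(co, probe), eq)),
               n_bmi(select_normal_subset(co, eq)) + 1)
})

test_that("disease injection depresses the normal fraction as configured", {
  # with decisive shrink factors the injected records cannot sit inside the
  # normal z-range, so the development subset is nearly free of them and
  # its size tracks the configured normal fraction
  truth <- default_truth()
  truth$obstruction_shrink <- c(0.5, 0.7)
  truth$restriction_shrink <- c(0.5, 0.7)
  co <- generate_cohort(small_strata(400, 200), truth, seed = 33)
  di <- inject_disease(co, truth, seed = 34)
  eq <- derive_equation_set(truth, race_specific = FALSE)
  sub <- select_normal_subset(di, eq)
  frac_injected_surviving <- mean(sub$id %in% di$id[di$true_pattern != "normal"])
  expect_lt(frac_injected_surviving, 0.05)
  # subset cannot exceed the uninjected fraction, and the BMI/z screens on
  # healthy records should not empty it
  expect_lt(nrow(sub) / nrow(di), 0.66)
  expect_gt(nrow(sub) / nrow(di), 0.25)
})

test_that("LASSO screening recovers true signals and drops noise", {
  d <- toy_truth_cohort(n = 900, race_offset = 0.5, sigma = 0.25, seed = 41)
  sel <- lasso_select(d, "FVC", seed = 1)
  expect_true("race" %in% sel)
  expect_true(any(c("height", "height2") %in% sel))
  # deterministic given seed
  expect_identical(sel, lasso_select(d, "FVC", seed = 1))

  # single-covariate pool returns it when truly associated
  sel1 <- lasso_select(d, "FVC", pool = "height2", seed = 1)
  expect_equal(as.character(sel1), "height2")

  # constant covariate columns are dropped with a warning
  d2 <- d; d2$sex <- "male"
  expect_warning(lasso_select(d2, "FVC", seed = 1), "constant")

  # sample-size precondition
  expect_error(lasso_select(d[1:50, ], "FVC", seed = 1), "at least")
})

test_that("race is not systematically retained under a null race effect", {
  # the min-CV penalty is deliberately liberal (screening before an OLS
  # refit), so the no-systematic-retention property is assessed under the
  # conservative one-SE rule
  hits <- 0L
  for (s in 1:12) {
    d <- toy_truth_cohort(n = 600, race_offset = 0, sigma = 0.3, seed = 100 + s)
    sel <- lasso_select(d, "FVC", seed = s, rule = "1se")
    hits <- hits + ("race" %in% sel)
  }
  expect_lt(hits / 12, 0.5)
})

test_that("OLS fitting recovers a noiseless truth exactly", {
  d <- toy_truth_cohort(n = 300, race_offset = 0.4, sigma = 0, seed = 51)
  # a zero-noise fit legitimately triggers the "perfect fit" lm warning
  fit <- suppressWarnings(
    fit_reference_model(d, "FVC", c("age", "height2", "sex", "race"),
                        trim = FALSE))
  est <- suppressWarnings(tidy(fit))
  expect_equal(unname(est$estimate[est$term == "age"]), -0.02,
               tolerance = 1e-8)
  expect_equal(unname(est$estimate[est$term == "height2"]), 0.00025,
               tolerance = 1e-8)
  expect_equal(unname(est$estimate[est$term == "raceBlack"]), -0.4,
               tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("studentized-residual trimming removes exactly the gross outlier", {
  d <- toy_truth_cohort(n = 300, race_offset = 0, sigma = 0.2, seed = 52)
  d$fvc[17] <- d$fvc[17] + 5  # far beyond 3 residual SDs
  fit <- fit_reference_model(d, "FVC", c("age", "height2", "sex"), trim = TRUE)
  expect_equal(fit$n_trimmed, 1)
  expect_false(fit$kept[17])
  # trimming never inflates the residual SD
  fit0 <- fit_reference_model(d, "FVC", c("age", "height2", "sex"),
                              trim = FALSE)
  expect_lte(fit$sigma, fit0$sigma)
})

test_that("the Gaussian BIC difference matches an independent computation", {
  d <- toy_truth_cohort(n = 500, race_offset = 0.3, sigma = 0.3, seed = 53)
  fit_big <- fit_reference_model(d, "FVC", c("age", "height2", "sex", "race"),
                                 trim = FALSE)
  fit_small <- fit_reference_model(d, "FVC", c("age", "height2", "sex"),
                                   trim = FALSE)
  # textbook recomputation from the stored RSS/k/n
  delta_own <- with(list(a = fit_small, b = fit_big),
                    (a$n * log(a$rss / a$n) + a$k * log(a$n)) -
                      (b$n * log(b$rss / b$n) + b$k * log(b$n)))
  expect_equal(fit_small$bic - fit_big$bic, delta_own, tolerance = 1e-10)
  # and agrees with stats::BIC on the underlying lm objects (constants cancel)
  delta_stats <- BIC(fit_small$model) - BIC(fit_big$model)
  expect_equal(fit_small$bic - fit_big$bic, delta_stats, tolerance = 1e-8)
  # adding a covariate never decreases R^2
  expect_gte(fit_big$r_squared, fit_small$r_squared)
})

test_that("BIC differences are invariant to response units", {
  d <- toy_truth_cohort(n = 400, race_offset = 0.3, sigma = 0.3, seed = 54)
  delta_l <- race_necessity_test(d, "FVC", c("age", "height2", "sex", "race"),
                                 trim = FALSE)$delta_bic
  d_ml <- d; d_ml$fvc <- d_ml$fvc * 1000
  delta_ml <- race_necessity_test(d_ml, "FVC",
                                  c("age", "height2", "sex", "race"),
                                  trim = FALSE)$delta_bic
  expect_equal(delta_l, delta_ml, tolerance = 1e-8)
})

test_that("rank-deficient designs error naming the collinear column", {
  d <- toy_truth_cohort(n = 200, seed = 55)
  d$height <- 170  # height constant => height2 constant too
  expect_error(fit_reference_model(d, "FVC", c("height", "height2"),
                                   trim = FALSE),
               class = "spiro_rank_error")
})

test_that("VIF screen flags constructed collinearity but exempts families", {
  set.seed(61)
  n <- 400
  d <- tibble::tibble(
    race = "White", sex = sample(c("male", "female"), n, TRUE),
    age = runif(n, 20, 90), height = rnorm(n, 170, 20),
    weight = rnorm(n, 80, 12), fvc = rnorm(n))
  # independent covariates: VIF near 1
  v <- vif_screen(d, c("age", "weight"), n_boot = 200, seed = 1)
  expect_true(all(v$vif < 1.2))
  expect_true(all(v$vif >= 1))
  expect_false(any(v$remove))

  # near-duplicate covariate: VIF >> 10, flagged
  d2 <- d; d2$weight <- 0.999 * d2$age + rnorm(n, 0, 0.01)
  v2 <- vif_screen(d2, c("age", "weight"), n_boot = 200, seed = 1)
  expect_true(all(v2$vif > 10))
  expect_true(any(v2$remove))

  # age and age2 alone: high VIF tolerated via the polynomial-family rule
  v3 <- vif_screen(d, c("age", "age2"), n_boot = 200, seed = 1)
  expect_true(any(v3$vif > 10))
  expect_true(all(v3$family_exempt))
  expect_false(any(v3$remove))

  # perfect collinearity is reported as infinite, flagged
  d4 <- d; d4$weight <- 2 * d4$age
  v4 <- vif_screen(d4, c("age", "weight"), n_boot = 50, seed = 1)
  expect_true(all(is.infinite(v4$vif)))
  expect_true(all(v4$remove))
})

test_that("the race-necessity test detects a real offset and not a null one", {
  d <- toy_truth_cohort(n = 1500, race_offset = 0.4, sigma = 0.4, seed = 71)
  rt <- race_necessity_test(d, "FVC", c("age", "height2", "sex", "race"))
  expect_gt(rt$delta_bic, 10)
  expect_equal(rt$evidence, "very strong")
  expect_equal(rt$favors, "include_race")
  expect_lte(rt$race_delta_r2, 0.1)

  d0 <- toy_truth_cohort(n = 1500, race_offset = 0, sigma = 0.4, seed = 72)
  rt0 <- race_necessity_test(d0, "FVC", c("age", "height2", "sex", "race"))
  expect_lt(rt0$delta_bic, 2)
  expect_equal(rt0$favors, "exclude_race")

  # single-race subset errors
  expect_error(race_necessity_test(d[d$race == "White", ], "FVC",
                                   c("age", "race")),
               class = "spiro_config_error")
  # covariates must include race
  expect_error(race_necessity_test(d, "FVC", c("age", "height2")), "race")
})

test_that("raftery labels bin as published", {
  expect_equal(raftery_label(c(0.5, 3, 8, 15)),
               c("weak", "positive", "strong", "very strong"))
  expect_error(raftery_label(-1), "non-negative")
})
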