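test_that("cohort generation is deterministic and seed-sensitive", {
  s <- small_strata(120, 60)
  c1 <- generate_cohort(s, seed = 91)
  c2 <- generate_cohort(s, seed = 91)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- generate_cohort(s, seed = 92)
  expect_false(identical(c1$fvc, c3$fvc))

  # empty strata give an empty, well-formed cohort
  s0 <- s; s0$n <- 0L
  c0 <- generate_cohort(s0, seed = 1)
  expect_equal(nrow(c0), 0)
  expect_true(all(c("id", "fev1", "fvc", "ratio") %in% names(c0)))
})

test_that("generated records respect physiology and configured ranges", {
  s <- small_strata(300, 150, 150)
  co <- generate_cohort(s, seed = 93)
  expect_true(all(co$fev1 < co$fvc))
  expect_true(all(co$ratio >= 0.18 - 1e-12 & co$ratio <= 0.95 + 1e-12))
  expect_true(all(co$age >= 18))
  for (i in seq_len(nrow(s))) {
    rows <- co$race == s$race[i] & co$sex == s$sex[i]
    if (!any(rows)) next
    expect_true(all(co$height[rows] >= s$height_min[i] &
                      co$height[rows] <= s$height_max[i]))
    expect_true(all(co$weight[rows] >= s$weight_min[i] &
                      co$weight[rows] <= s$weight_max[i]))
  }
  expect_equal(co$bmi, co$weight / (co$height / 100)^2)
  # truth log covers every record
  expect_equal(truth_log(co)$id, co$id)
})

test_that("truncated-normal demographics match their stratum moments", {
  s <- default_strata()[1, ]  # White males: height 178 (8), range 149-206
  s$n <- 10000L
  co <- generate_cohort(s, seed = 94)
  expect_equal(mean(co$height), 178, tolerance = 0.3 / 178)
  expect_equal(sd(co$height), 8, tolerance = 0.05)

  # infeasible truncation is a config error
  s_bad <- s; s_bad$height_min <- 300
  expect_error(generate_cohort(s_bad, seed = 1),
               class = "spiro_config_error")
})

test_that("race offsets follow the configured height-linear profiles", {
  tr <- default_truth()
  expect_equal(race_offset(tr, "Black", "FVC", c(140, 185)), c(0.40, 0.70))
  expect_equal(race_offset(tr, "Black", "FEV1", c(140, 185)), c(0.27, 0.48))
  expect_equal(race_offset(tr, "Hispanic", "FEV1", c(140, 185)), c(0.56, 0.56))
  expect_equal(race_offset(tr, "Hispanic", "FVC", c(140, 175, 185)),
               c(0.25, 0, 0))
  expect_equal(race_offset(tr, "White", "FVC", 170), 0)
  # scale knob switches effects off
  expect_equal(race_offset(default_truth(race_offset_scale = 0),
                           "Black", "FVC", 170), 0)
})

test_that("null offsets and vanishing noise give race-identical outcomes", {
  s <- small_strata(40, 40)
  # force identical covariate distributions across races so any FVC gap
  # could only come from a race offset
  for (col in c("age_mean", "height_mean", "weight_mean")) {
    white <- s[[col]][s$race == "White"]
    s[[col]] <- ifelse(s$sex == "male", white[1], white[2])
  }
  s$age_sd <- s$height_sd <- s$weight_sd <- 1e-9
  tr <- default_truth(race_offset_scale = 0, sigma = 1e-9)
  tr$ratio_sd <- 1e-9
  co <- generate_cohort(s, tr, seed = 95)
  for (g in split(co, co$sex)) {
    if (length(unique(g$race)) < 2) next
    expect_lt(diff(range(tapply(g$fvc, g$race, mean))), 1e-3)
  }
})

test_that("disease injection hits its prevalence and shifts classifications", {
  s <- small_strata(600, 0)
  tr <- default_truth()
  co <- generate_cohort(s, tr, seed = 96)
  di <- inject_disease(co, tr, seed = 97)
  n <- nrow(di)
  n_obs <- sum(di$true_pattern == "obstruction")
  # binomial 99% bounds around 0.17 n
  expect_true(abs(n_obs - 0.17 * n) < 2.58 * sqrt(n * 0.17 * 0.83) + 1)

  # prevalence 0 leaves the cohort unchanged
  tr0 <- default_truth(obstruction_prevalence = 0, restriction_prevalence = 0)
  di0 <- inject_disease(co, tr0, seed = 98)
  expect_equal(di0$fev1, co$fev1)
  expect_equal(di0$fvc, co$fvc)
  expect_true(all(di0$true_pattern == "normal"))

  # prevalences summing beyond 1 are a config error
  expect_error(inject_disease(co, default_truth(obstruction_prevalence = 0.6,
                                                restriction_prevalence = 0.6)),
               class = "spiro_config_error")
})

test_that("a calibrated equation set detects strongly injected obstruction", {
  tr <- default_truth()
  tr$obstruction_shrink <- c(0.5, 0.6)  # strong shrink
  s <- small_strata(400, 200)
  co <- generate_cohort(s, tr, seed = 99)
  di <- inject_disease(co, tr, seed = 100)
  eq <- derive_equation_set(tr, race_specific = TRUE)
  calls <- classify_patterns(di, eq)
  truth_obs <- di$true_pattern == "obstruction"
  called_obs <- calls$pattern %in% c("obstruction", "mixed")
  expect_gt(mean(called_obs[truth_obs]), 0.9)
})

test_that("generator and race test are self-consistent about race evidence", {
  tr <- default_truth()
  tr$offsets$at140[tr$offsets$race == "Black" & tr$offsets$index == "FVC"] <- 0.4
  tr$offsets$at185[tr$offsets$race == "Black" & tr$offsets$index == "FVC"] <- 0.4
  s <- small_strata(700, 300)
  co <- generate_cohort(s, tr, seed = 101)
  rt <- race_necessity_test(co, "FVC", c("age", "height2", "sex", "race"),
                            trim = FALSE)
  expect_gt(rt$delta_bic, 10)
  expect_equal(rt$evidence, "very strong")

  tr0 <- default_truth(race_offset_scale = 0)
  co0 <- generate_cohort(s, tr0, seed = 102)
  rt0 <- race_necessity_test(co0, "FVC", c("age", "height2", "sex", "race"),
                             trim = FALSE)
  expect_lt(rt0$delta_bic, 10)
})
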