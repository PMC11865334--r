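test_that("coefficient tables validate their schema and vocabulary", {
  # smallest legal polynomial table
  eq <- poly_table("FEV1", "female", "demo",
                   predicted = c(intercept = 4), lln = c(intercept = 3))
  expect_s3_class(eq, "spiro_equations")
  expect_equal(evaluate_polynomial(eq, 50, 170, "FEV1", "female", "demo"),
               tibble::tibble(predicted = 4, lln = 3, uln = 5))

  # closed covariate vocabulary
  expect_error(
    poly_table("FEV1", "female", "demo",
               predicted = c(weight3 = 1), lln = c(intercept = 3)),
    class = "spiro_schema_error")
  expect_error(
    lms_table("FVC", "male", "x", m = c(bmi = 1),
              s = c(intercept = 0), l = c(intercept = 1)),
    class = "spiro_schema_error")

  # missing blocks are named
  bad <- toy_poly_eq()
  expect_error(validate_equations(bad[bad$block != "lln", ]),
               "missing block: lln", class = "spiro_validation_error")
  lms <- toy_lms_eq()
  expect_error(validate_equations(lms[lms$block != "s", ]),
               "missing block: s", class = "spiro_schema_error")

  # non-monotone spline grid rejected
  sp <- tibble::tibble(age = c(30, 30), m = c(0, 0.1), s = c(0, 0))
  expect_error(toy_lms_eq(spline = sp), class = "spiro_validation_error")
})

test_that("equation sets round-trip through the delimited format", {
  eq <- equation_set(
    toy_lms_eq(spline = tibble::tibble(age = c(20, 45.5, 80),
                                       m = c(0.02, -0.013, 0.06),
                                       s = c(0.001, 0.0205, -0.03))),
    poly_table("FEV1", "female", "ref",
               predicted = c(intercept = 1.23456789012345,
                             age = -0.0123, height2 = 9.87e-5),
               lln = c(intercept = 0.9, age = -0.0123, height2 = 9.87e-5)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_equations(eq, path)
  back <- read_equations(path)
  expect_equal(as.data.frame(back), as.data.frame(eq))

  expect_error(read_equations(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("LMS evaluation matches hand oracles at and between knots", {
  # no spline: exp/ln identity
  eq0 <- toy_lms_eq()
  expect_equal(evaluate_lms(eq0, 50, 170, "FVC", "male", "demo")$M, 4.0)

  sp <- tibble::tibble(age = c(20, 40, 60), m = c(0.02, 0.06, 0.10),
                       s = c(0, 0, 0))
  eq <- toy_lms_eq(spline = sp)
  # exactly on a knot: tabulated value
  expect_equal(evaluate_lms(eq, 40, 170, "FVC", "male", "demo")$M,
               4 * exp(0.06), tolerance = 1e-12)
  # midway between knots under linear interpolation: hand value 0.04
  got <- evaluate_lms(eq, 30, 170, "FVC", "male", "demo", interp = "linear")
  expect_equal(got$M, 4 * exp(0.04), tolerance = 1e-12)
  # cubic interpolation of knot values lying on a line is exact too
  expect_equal(evaluate_lms(eq, 30, 170, "FVC", "male", "demo")$M,
               4 * exp(0.04), tolerance = 1e-10)

  # outside the grid: error by default, clamp with warning when allowed
  expect_error(evaluate_lms(eq, 90, 170, "FVC", "male", "demo"),
               class = "spiro_range_error")
  expect_warning(
    clamped <- evaluate_lms(eq, 90, 170, "FVC", "male", "demo",
                            allow_extrapolation = TRUE),
    "clamped")
  expect_equal(clamped$M, 4 * exp(0.10), tolerance = 1e-12)

  # height and age covariate terms contribute as specified
  eq2 <- lms_table("FVC", "male", "demo",
                   m = c(intercept = 0.5, log_height = 2, log_age = -0.1,
                         age = 0.001),
                   s = c(intercept = log(0.1)), l = c(intercept = 0.9))
  got2 <- evaluate_lms(eq2, 50, 170, "FVC", "male", "demo")
  expect_equal(got2$M,
               exp(0.5 + 2 * log(170) - 0.1 * log(50) + 0.001 * 50),
               tolerance = 1e-12)
  expect_equal(got2$L, 0.9)
})

test_that("z-scores satisfy the algebraic oracles and limits", {
  # median case
  z0 <- zscore(4, 1, 4, 0.1)
  expect_equal(z0$z, 0)
  expect_equal(z0$percentile, 0.5)

  # L = 1 closed form: z = (x - M)/(M S) = -1.645 here, exactly at the LLN
  z1 <- zscore(3.342, 1, 4, 0.1)
  expect_equal(z1$z, (3.342 - 4) / 0.4, tolerance = 1e-12)
  expect_equal(z1$z, -1.645, tolerance = 1e-9)
  # any measurement strictly below that value is flagged
  expect_true(zscore(3.33, 1, 4, 0.1)$z < -1.645)

  # normal-quantile identity at the LLN
  expect_equal(pnorm(-1.645), 0.04998, tolerance = 1e-4)
  expect_equal(zscore(z1$lln, 1, 4, 0.1)$z, -1.645, tolerance = 1e-12)

  # domain errors
  expect_error(zscore(-1, 1, 4, 0.1), "positive")
  expect_error(zscore(3, 1, -4, 0.1), "positive")
})

test_that("round-trip value_at <-> zscore holds across an (L, M, S, z) grid", {
  grid <- expand.grid(L = c(-1.5, -0.3, 0, 1e-9, 0.5, 1, 2),
                      M = c(0.7, 3.2, 5.5), S = c(0.05, 0.12, 0.2),
                      z0 = seq(-3, 3, by = 0.5))
  v <- lms_value_at(grid$z0, grid$L, grid$M, grid$S)
  ok <- is.finite(v) & v > 0  # extreme z with large |L|S can leave the support
  expect_gt(mean(ok), 0.95)
  z <- zscore(v[ok], grid$L[ok], grid$M[ok], grid$S[ok])$z
  expect_equal(z, grid$z0[ok], tolerance = 1e-10)
})

test_that("z is continuous through L = 0 and monotone in the measurement", {
  grid <- expand.grid(M = c(2, 4), S = c(0.08, 0.15),
                      x = c(1.5, 3, 4.5))
  z_small <- zscore(grid$x, 1e-9, grid$M, grid$S)$z
  z_limit <- zscore(grid$x, 0, grid$M, grid$S)$z
  expect_equal(z_small, z_limit, tolerance = 1e-6)

  xs <- seq(1, 6, by = 0.05)
  for (L in c(-0.5, 0, 1.2)) {
    zz <- zscore(xs, L, 4, 0.1)$z
    expect_true(all(diff(zz) > 0))
  }
  r <- zscore(3.9, 0.8, 4, 0.1)
  expect_true(r$lln < r$M && r$M < r$uln)
})

test_that("an LMS table with L = 1 reproduces the linear-SD closed form", {
  # with L = 1: z = (x - M)/(M S), so LLN = M (1 - 1.645 S); a polynomial
  # table with predicted = M and that LLN yields the identical pseudo-z
  M <- 4.2; S <- 0.11
  x <- seq(2.5, 5.5, by = 0.25)
  z_lms <- zscore(x, 1, M, S)$z
  z_poly <- poly_pseudo_z(x, predicted = M, lln = M * (1 - 1.645 * S))
  expect_equal(z_lms, z_poly, tolerance = 1e-12)
})

test_that("polynomial evaluation matches hand arithmetic and boundary rule", {
  eq <- toy_poly_eq()
  got <- evaluate_polynomial(eq, 50, 170, "FVC", "male", "demo")
  expect_equal(got$predicted, 1 + 0.5 + 2.89, tolerance = 1e-12)
  expect_equal(got$lln, 0.5 + 2.89, tolerance = 1e-12)

  # measured exactly at the LLN is NOT below it (strict inequality)
  z <- poly_pseudo_z(got$lln, got$predicted, got$lln)
  expect_equal(z, -1.645)
  expect_false(z < -1.645)

  expect_error(poly_pseudo_z(3, predicted = 3, lln = 3.5), "exceed")
})
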