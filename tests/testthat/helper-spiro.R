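# shared fixtures, all built in code

# LMS table with a non-trivial spline grid; M = exp(log 4 + spline_m(age)),
# S = exp(log 0.1 + spline_s(age)), L = 1
toy_lms_eq <- function(spline = NULL) {
  lms_table("FVC", "male", "demo",
            m = c(intercept = log(4)),
            s = c(intercept = log(0.1)),
            l = c(intercept = 1),
            spline = spline)
}

# polynomial table: predicted = 1 + 0.01 age + 1e-4 height^2, LLN 1 L lower
toy_poly_eq <- function() {
  poly_table("FVC", "male", "demo",
             predicted = c(intercept = 1, age = 0.01, height2 = 1e-4),
             lln = c(intercept = 0, age = 0.01, height2 = 1e-4))
}

# tiny raw cohort exercising every screening rule
toy_raw_cohort <- function() {
  tibble::tibble(
    id = c("a", "a", "b", "c", "d", "e", "f"),
    race = c("White", "White", "Black", "other", "White", "Hispanic", "White"),
    sex = c("male", "male", "female", "male", "female", "male", "male"),
    age = c(50, 51, 60, 40, 17, 70, 55),
    height = c(175, 175, 160, 180, 165, 170, 172),
    weight = c(80, 80, 65, 90, 60, 75, NA),
    fev1 = c(3.0, 2.9, 2.0, 3.5, 2.5, 2.2, 3.0),
    fvc = c(4.0, 3.9, 2.8, 4.5, 3.2, 3.0, 4.0),
    svc = c(4.4, NA, 2.5, NA, NA, 3.3, NA),
    visit = c(2, 1, 1, 1, 1, 1, 1))
}

# small two-race cohort with a known linear truth for model-fitting tests
toy_truth_cohort <- function(n = 400, race_offset = 0.4, sigma = 0.3,
                             seed = 1) {
  set.seed(seed)
  race <- sample(c("White", "Black"), n, replace = TRUE, prob = c(0.7, 0.3))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  age <- runif(n, 20, 90)
  height <- rnorm(n, ifelse(sex == "male", 176, 162), 7)
  weight <- rnorm(n, 80, 12)
  mu <- -2.4 + 0.00025 * height^2 - 0.02 * age + 0.1 * (sex == "male") -
    race_offset * (race == "Black")
  fvc <- mu + rnorm(n, 0, sigma)
  ratio <- pmin(pmax(rnorm(n, 0.78, 0.05), 0.2), 0.94)
  tibble::tibble(id = as.character(seq_len(n)), race = race, sex = sex,
                 age = age, height = height, weight = weight,
                 bmi = weight / (height / 100)^2,
                 fev1 = ratio * fvc, fvc = fvc, svc = NA_real_, visit = 1L,
                 ratio = ratio)
}

# small strata table for fast synthetic cohorts
small_strata <- function(n_white = 200, n_black = 200, n_hispanic = 0) {
  s <- default_strata()
  s$n <- 0L
  s$n[s$race == "White"] <- c(ceiling(n_white / 2), floor(n_white / 2))
  s$n[s$race == "Black"] <- c(ceiling(n_black / 2), floor(n_black / 2))
  s$n[s$race == "Hispanic"] <- c(ceiling(n_hispanic / 2), floor(n_hispanic / 2))
  s
}
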