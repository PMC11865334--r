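# Cohort ingestion, screening and pattern classification.

RACES <- c("White", "Black", "Hispanic")

# accept both the documented file header (height_cm, fev1_l, ...) and the
# canonical internal names; returns a tibble with canonical names
normalize_cohort_names <- function(raw) {
  raw <- dplyr::as_tibble(raw)
  map <- c(height_cm = "height", weight_kg = "weight",
           fev1_l = "fev1", fvc_l = "fvc", svc_l = "svc")
  for (from in names(map)) {
    if (from %in% names(raw) && !map[[from]] %in% names(raw)) {
      names(raw)[names(raw) == from] <- map[[from]]
    }
  }
  raw
}

#' Read a cohort file
#'
#' Reads the documented delimited cohort format: a header row and columns
#' `id, race, sex, age, height_cm, weight_kg, fev1_l, fvc_l, svc_l, visit`
#' (missing SVC as an empty field). Column names are normalized to the
#' package-internal `height`, `weight`, `fev1`, `fvc`, `svc`.
#'
#' @param path Path to a tab- or comma-delimited cohort file.
#' @return A tibble of raw records (not yet screened; see
#'   [prepare_records()]).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("cohort file not found: ", path))
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  normalize_cohort_names(
    readr::read_delim(path, delim = delim, show_col_types = FALSE))
}

#' Screen and prepare raw spirometry records
#'
#' Applies the study screening rules to a raw record table:
#' * rows with any key field missing or non-numeric are excluded (logged,
#'   never a crash);
#' * age under 18 and races outside White/Black/Hispanic are excluded;
#' * when a slow vital capacity (SVC) exceeds the FVC, the SVC replaces
#'   the FVC and the FEV1/FVC ratio is recomputed;
#' * only the first available test (minimal `visit`) is kept per `id`;
#'   when no visit column is present, file order defines visit order.
#'
#' BMI and the FEV1/FVC ratio are derived, never read from the file, so
#' height/weight/BMI stay mutually consistent.
#'
#' @param raw A data frame of raw records (see [read_cohort()] for the
#'   expected columns; `svc` and `visit` optional).
#' @return A prepared tibble with derived `bmi` and `ratio` columns and an
#'   `exclusions` attribute (a tibble of counts by reason) retrievable via
#'   [exclusion_log()].
#' @export
prepare_records <- function(raw) {
  raw <- normalize_cohort_names(raw)
  n_input <- nrow(raw)
  key <- c("id", "race", "sex", "age", "height", "weight", "fev1", "fvc")
  missing_cols <- setdiff(key, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("cohort is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (!"svc" %in% names(raw)) raw$svc <- NA_real_
  if (!"visit" %in% names(raw)) raw$visit <- seq_len(nrow(raw))

  to_num <- function(x) suppressWarnings(as.numeric(x))
  raw <- dplyr::mutate(raw,
    dplyr::across(dplyr::all_of(c("age", "height", "weight", "fev1", "fvc",
                                  "svc", "visit")), to_num),
    race = as.character(.data$race), sex = as.character(.data$sex),
    id = as.character(.data$id))

  reasons <- character(nrow(raw))
  bad_key <- !complete.cases(raw[, key]) |
    raw$fev1 <= 0 | raw$fvc <= 0 | raw$height <= 0 | raw$weight <= 0
  bad_key[is.na(bad_key)] <- TRUE
  reasons[bad_key] <- "missing_or_invalid_key_data"
  under_age <- !bad_key & raw$age < 18
  reasons[under_age] <- "age_under_18"
  other_race <- !bad_key & !under_age & !raw$race %in% RACES
  reasons[other_race] <- "race_other"

  kept <- raw[reasons == "", ]
  excl <- tibble::tibble(reason = reasons[reasons != ""])

  # SVC substitution, then first-visit dedup, then derived fields
  kept <- dplyr::mutate(kept,
    fvc = dplyr::if_else(!is.na(.data$svc) & .data$svc > .data$fvc,
                         .data$svc, .data$fvc))
  n_before <- nrow(kept)
  kept <- kept |>
    dplyr::group_by(.data$id) |>
    dplyr::slice_min(.data$visit, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$visit)
  n_dedup <- n_before - nrow(kept)

  bad_ratio <- kept$fev1 > kept$fvc
  n_bad_ratio <- sum(bad_ratio)
  kept <- kept[!bad_ratio, ]

  kept <- dplyr::mutate(kept,
    bmi = .data$weight / (.data$height / 100)^2,
    ratio = .data$fev1 / .data$fvc)

  log <- dplyr::count(excl, .data$reason, name = "n")
  if (n_bad_ratio > 0) {
    log <- dplyr::bind_rows(log, tibble::tibble(reason = "fev1_exceeds_fvc",
                                                n = n_bad_ratio))
  }
  if (n_dedup > 0) {
    log <- dplyr::bind_rows(log, tibble::tibble(reason = "repeat_visit", n = n_dedup))
  }
  attr(kept, "exclusions") <- log
  attr(kept, "n_input") <- n_input
  kept
}

#' Exclusion log of a prepared cohort
#'
#' @param x A tibble returned by [prepare_records()] or
#'   [select_normal_subset()].
#' @return A tibble with columns `reason` and `n`.
#' @export
exclusion_log <- function(x) {
  attr(x, "exclusions") %||% tibble::tibble(reason = character(), n = integer())
}

#' Attach z-scores from an equation set to a cohort
#'
#' Evaluates the equation set for every record and all three indices
#' (FEV1, FVC, FEV1/FVC), adding `z_*`, `pred_*` and `lln_*` columns.
#' Polynomial-engine tables contribute pseudo z-scores (see
#' [poly_pseudo_z()]).
#'
#' @param data A prepared cohort tibble with `sex`, `age`, `height`,
#'   `fev1`, `fvc` (and `race` when `population = NULL`).
#' @param equations A `spiro_equations` tibble.
#' @param population `NULL` to match each record's `race` to the table
#'   `population` label (race-specific use), or a single label (e.g.
#'   `"race-neutral"`) applied to every record.
#' @inheritParams evaluate_lms
#' @return `data` with nine added columns.
#' @export
add_zscores <- function(data, equations, population = NULL,
                        interp = c("cubic", "linear"),
                        allow_extrapolation = FALSE) {
  interp <- match.arg(interp)
  data <- dplyr::as_tibble(data)
  if (!"ratio" %in% names(data)) data$ratio <- data$fev1 / data$fvc
  pop <- if (is.null(population)) as.character(data$race) else
    rep_len(population, nrow(data))
  measured_col <- c(FEV1 = "fev1", FVC = "fvc", FEV1_FVC = "ratio")
  suffix <- c(FEV1 = "fev1", FVC = "fvc", FEV1_FVC = "ratio")
  for (sfx in suffix) {
    data[[paste0("z_", sfx)]] <- NA_real_
    data[[paste0("pred_", sfx)]] <- NA_real_
    data[[paste0("lln_", sfx)]] <- NA_real_
  }
  groups <- split(seq_len(nrow(data)), paste(data$sex, pop, sep = "|"))
  for (idx in names(groups)) {
    rows <- groups[[idx]]
    sex_g <- data$sex[rows[1]]
    pop_g <- pop[rows[1]]
    for (index in EQ_INDICES) {
      g <- eq_subset(equations, index, sex_g, pop_g)
      sfx <- suffix[[index]]
      measured <- data[[measured_col[[index]]]][rows]
      if (unique(g$engine) == "lms") {
        lms <- evaluate_lms(equations, data$age[rows], data$height[rows],
                            index, sex_g, pop_g, interp = interp,
                            allow_extrapolation = allow_extrapolation)
        zr <- zscore(measured, lms$L, lms$M, lms$S)
        data[[paste0("z_", sfx)]][rows] <- zr$z
        data[[paste0("pred_", sfx)]][rows] <- zr$predicted
        data[[paste0("lln_", sfx)]][rows] <- zr$lln
      } else {
        pl <- evaluate_polynomial(equations, data$age[rows], data$height[rows],
                                  index, sex_g, pop_g)
        data[[paste0("z_", sfx)]][rows] <-
          poly_pseudo_z(measured, pl$predicted, pl$lln)
        data[[paste0("pred_", sfx)]][rows] <- pl$predicted
        data[[paste0("lln_", sfx)]][rows] <- pl$lln
      }
    }
  }
  data
}

#' Classify obstructive / restrictive spirometric patterns
#'
#' Adds z-scores under one equation set and assigns each record one of
#' four mutually exclusive pattern labels, using the lower limit of
#' normal at z = −1.645 (5th centile) with strict inequality:
#' * `obstruction`: z(FEV1/FVC) < −1.645 and z(FVC) ≥ −1.645;
#' * `restrictive`: z(FEV1/FVC) ≥ −1.645 and z(FVC) < −1.645;
#' * `mixed`: both below;
#' * `normal`: neither below.
#'
#' Note the obstruction definition is the standard one (ratio below its
#' LLN). Also adds logical `below_lln_*` flags for the three indices.
#'
#' @inheritParams add_zscores
#' @param label Text recorded in the `equations_label` column.
#' @return `data` with z-score, flag, `pattern` and `equations_label`
#'   columns.
#' @export
classify_patterns <- function(data, equations, population = NULL,
                              interp = c("cubic", "linear"),
                              allow_extrapolation = FALSE,
                              label = if (is.null(population)) "race-specific"
                                      else population) {
  data <- add_zscores(data, equations, population = population,
                      interp = interp,
                      allow_extrapolation = allow_extrapolation)
  dplyr::mutate(data,
    below_lln_fev1 = .data$z_fev1 < LLN_Z,
    below_lln_fvc = .data$z_fvc < LLN_Z,
    below_lln_ratio = .data$z_ratio < LLN_Z,
    pattern = dplyr::case_when(
      .data$below_lln_ratio & !.data$below_lln_fvc ~ "obstruction",
      !.data$below_lln_ratio & .data$below_lln_fvc ~ "restrictive",
      .data$below_lln_ratio & .data$below_lln_fvc ~ "mixed",
      TRUE ~ "normal"),
    equations_label = label)
}

#' Positive-call vector for one pattern
#'
#' @param calls A tibble from [classify_patterns()].
#' @param pattern `"obstruction"`, `"restrictive"`, `"fev1"` or `"fvc"`
#'   (the latter two meaning the index below its LLN).
#' @param include_mixed Count `mixed` records as obstructed (default
#'   `FALSE`, matching an obstruction definition that requires FVC ≥ LLN).
#' @return Logical vector, one element per record.
#' @export
pattern_positive <- function(calls, pattern, include_mixed = FALSE) {
  switch(pattern,
    obstruction = calls$pattern == "obstruction" |
      (include_mixed & calls$pattern == "mixed"),
    restrictive = calls$pattern == "restrictive",
    fev1 = calls$below_lln_fev1,
    fvc = calls$below_lln_fvc,
    rlang::abort(paste0("unknown pattern: ", pattern)))
}
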