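# End-to-end pipeline driver: prepare -> classify (benchmark,
# alternative) -> concordance -> optional develop/validate -> project,
# with delimited reports and a structured run manifest.

#' Pipeline configuration
#'
#' Collects everything one run needs. The cohort comes either from a
#' delimited file (`cohort_file`) or from the synthetic generator
#' (`simulate = TRUE`). Equation sets may be supplied as
#' `spiro_equations` tibbles or file paths; when omitted and
#' `simulate = TRUE`, calibrated synthetic sets are derived from the
#' truth model. Every source of randomness descends from `seed`.
#'
#' @param cohort_file Optional path to a cohort file.
#' @param simulate Generate a synthetic cohort when no file is given.
#' @param strata,truth Generator configuration (see [default_strata()],
#'   [default_truth()]).
#' @param inject Inject disease into the synthetic cohort.
#' @param benchmark_equations,alternative_equations `spiro_equations`
#'   tibbles or file paths; `NULL` means derive from `truth`.
#' @param benchmark_population `NULL` (race-specific: match each record's
#'   race) or a fixed population label.
#' @param alternative_population Population label of the alternative set
#'   (default `"race-neutral"`).
#' @param patterns Patterns to compare (default all four).
#' @param develop Run the race-necessity analysis.
#' @param develop_responses Responses for it (default FEV1 and FVC).
#' @param race_pair Two race labels for develop/validate stages.
#' @param validate Run CV + permutation + bootstrap.
#' @param cv_k,cv_repeats,n_perm,n_boot,resample_cv_repeats Validation
#'   sizes.
#' @param projection Optional list with `population`, `tests_per_10k`,
#'   `error_rate` for the projection stage.
#' @param seed Master seed.
#' @param out_dir Optional directory for delimited reports + manifest.
#' @return A `spiro_config` list.
#' @export
pipeline_config <- function(cohort_file = NULL, simulate = is.null(cohort_file),
                            strata = default_strata(), truth = default_truth(),
                            inject = TRUE,
                            benchmark_equations = NULL,
                            alternative_equations = NULL,
                            benchmark_population = NULL,
                            alternative_population = "race-neutral",
                            patterns = c("obstruction", "restrictive",
                                         "fev1", "fvc"),
                            develop = TRUE,
                            develop_responses = c("FEV1", "FVC"),
                            race_pair = c("Black", "White"),
                            validate = FALSE, cv_k = 10, cv_repeats = 100,
                            n_perm = 199, n_boot = 199,
                            resample_cv_repeats = 5,
                            projection = NULL, seed = 1, out_dir = NULL) {
  cfg <- as.list(environment())
  if (!is.null(cohort_file) && !file.exists(cohort_file)) {
    rlang::abort(paste0("cohort file does not exist: ", cohort_file))
  }
  for (f in c("benchmark_equations", "alternative_equations")) {
    if (is.character(cfg[[f]]) && !file.exists(cfg[[f]])) {
      rlang::abort(paste0(f, " file does not exist: ", cfg[[f]]))
    }
  }
  structure(cfg, class = "spiro_config")
}

resolve_equations <- function(x, truth, strata, race_specific) {
  if (is.null(x)) return(derive_equation_set(truth, strata, race_specific))
  if (is.character(x)) return(read_equations(x))
  validate_equations(x)
}

#' Run the full analysis pipeline
#'
#' Executes prepare -> classify under the benchmark and alternative
#' equation sets -> per-pattern (and per-race) concordance reports ->
#' optional equation development with the race-necessity BIC test ->
#' optional cross-validation with permutation/bootstrap RMSE tests ->
#' optional population projection. Any stage failure aborts with the
#' stage name. When `config$out_dir` is set, tab-separated reports and a
#' JSON run manifest are written there; reruns with the same config are
#' byte-identical.
#'
#' @param config A `spiro_config` list from [pipeline_config()].
#' @return (Invisibly) a list with elements `cohort`, `calls_benchmark`,
#'   `calls_alternative`, `discordance`, `develop`, `validate`,
#'   `projection`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "spiro_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)), parent = e)
    })
  }
  manifest <- list(package_version = as.character(utils::packageVersion("spirodiscord")),
                   seed = config$seed, stages = list())

  raw <- stage("cohort", {
    if (!is.null(config$cohort_file)) {
      read_cohort(config$cohort_file)
    } else if (isTRUE(config$simulate)) {
      co <- generate_cohort(config$strata, config$truth, seed = config$seed)
      if (isTRUE(config$inject)) {
        co <- inject_disease(co, config$truth, seed = config$seed + 1000L)
      }
      co
    } else {
      rlang::abort("no cohort source configured")
    }
  })
  manifest$stages$cohort <- list(n = nrow(raw))

  cohort <- stage("prepare", prepare_records(raw))
  manifest$stages$prepare <- list(
    n_input = attr(cohort, "n_input"), n_kept = nrow(cohort),
    exclusions = as.list(setNames(exclusion_log(cohort)$n,
                                  exclusion_log(cohort)$reason)))

  bench_eq <- stage("equations", resolve_equations(
    config$benchmark_equations, config$truth, config$strata,
    race_specific = TRUE))
  alt_eq <- stage("equations", resolve_equations(
    config$alternative_equations, config$truth, config$strata,
    race_specific = FALSE))

  calls_b <- stage("classify", classify_patterns(
    cohort, bench_eq, population = config$benchmark_population,
    label = "benchmark"))
  calls_a <- stage("classify", classify_patterns(
    cohort, alt_eq, population = config$alternative_population,
    label = "alternative"))
  manifest$stages$classify <- list(n = nrow(calls_b))

  discord <- stage("concordance", {
    groups <- c(list(all = rep(TRUE, nrow(calls_b))),
                setNames(purrr::map(RACES, ~ cohort$race == .x), RACES))
    purrr::imap(groups, function(idx, gname) {
      if (sum(idx) < 2) return(NULL)
      purrr::map(config$patterns, function(p) {
        b <- pattern_positive(calls_b[idx, ], p)
        a <- pattern_positive(calls_a[idx, ], p)
        # pattern-defining z under the alternative set; negated so larger
        # scores mean "more abnormal" (discriminating benchmark positives)
        sc <- switch(p,
          obstruction = calls_a$z_ratio[idx],
          restrictive = calls_a$z_fvc[idx],
          fev1 = calls_a$z_fev1[idx],
          fvc = calls_a$z_fvc[idx])
        out <- tryCatch(compare_classifications(b, a, scores = -sc),
                        error = function(e) NULL)
        if (is.null(out)) return(NULL)
        dplyr::mutate(out, group = gname, pattern = p, .before = 1)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  })

  dev_out <- NULL
  if (isTRUE(config$develop)) {
    dev_out <- stage("develop", {
      subset <- select_normal_subset(cohort, alt_eq,
                                     population = config$alternative_population)
      pair <- subset[subset$race %in% config$race_pair, ]
      purrr::map(config$develop_responses, function(resp) {
        sel <- lasso_select(pair, resp, seed = config$seed + 2000L)
        covs <- union(sel, "race")
        rt <- race_necessity_test(pair, resp, covs)
        dplyr::mutate(glance(rt),
                      covariates = paste(covs, collapse = "+"),
                      .before = 1)
      }) |> dplyr::bind_rows()
    })
    manifest$stages$develop <- list(n_rows = nrow(dev_out))
  }

  val_out <- NULL
  if (isTRUE(config$validate)) {
    val_out <- stage("validate", {
      subset <- select_normal_subset(cohort, alt_eq,
                                     population = config$alternative_population)
      pair <- subset[subset$race %in% config$race_pair, ]
      purrr::map(config$develop_responses, function(resp) {
        covs <- c("age", "height2", "sex", "race")
        cv <- repeated_cv(pair, resp, covs, k = config$cv_k,
                          repeats = config$cv_repeats,
                          seed = config$seed + 3000L)
        pt <- permutation_test_rmse(pair, resp, covs, k = config$cv_k,
                                    n_perm = config$n_perm,
                                    cv_repeats = config$resample_cv_repeats,
                                    seed = config$seed + 4000L)
        bt <- bootstrap_test_rmse(pair, resp, covs, k = config$cv_k,
                                  n_boot = config$n_boot,
                                  cv_repeats = config$resample_cv_repeats,
                                  seed = config$seed + 5000L)
        dplyr::bind_cols(glance(cv),
                         dplyr::rename_with(glance(pt), ~ paste0("perm_", .x)),
                         dplyr::rename_with(glance(bt), ~ paste0("boot_", .x)))
      }) |> dplyr::bind_rows()
    })
    manifest$stages$validate <- list(n_rows = nrow(val_out))
  }

  proj_out <- NULL
  if (!is.null(config$projection)) {
    proj_out <- stage("project", {
      p <- config$projection
      tests <- annual_tests(p$population, p$tests_per_10k)
      tibble::tibble(population = p$population,
                     tests_per_10k = p$tests_per_10k,
                     annual_tests = tests,
                     error_rate = p$error_rate,
                     projected_misclassifications =
                       projected_misclassifications(tests, p$error_rate))
    })
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(discord, file.path(config$out_dir, "discordance.tsv"))
    if (!is.null(dev_out)) {
      readr::write_tsv(dev_out, file.path(config$out_dir, "develop.tsv"))
    }
    if (!is.null(val_out)) {
      readr::write_tsv(val_out, file.path(config$out_dir, "validate.tsv"))
    }
    if (!is.null(proj_out)) {
      readr::write_tsv(proj_out, file.path(config$out_dir, "projection.tsv"))
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(list(cohort = cohort, calls_benchmark = calls_b,
                 calls_alternative = calls_a, discordance = discord,
                 develop = dev_out, validate = val_out,
                 projection = proj_out, manifest = manifest))
}
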