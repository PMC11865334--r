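# ggplot2 visualisations for the result objects.

#' Density plot of cross-validated RMSE
#'
#' @param object A `spiro_cv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spiro_cv
#' @export
autoplot.spiro_cv <- function(object, ...) {
  ggplot2::ggplot(object$per_repeat, ggplot2::aes(x = .data$rmse)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::labs(x = "held-out RMSE (L)", y = "density",
                  title = paste0("Repeated ", object$k, "-fold CV RMSE: ",
                                 object$response)) +
    ggplot2::theme_minimal()
}

#' Compare RMSE densities of two cross-validation runs
#'
#' The classic two-density comparison of a race-specific against a
#' race-neutral model's held-out RMSE distributions.
#'
#' @param cv_specific,cv_neutral `spiro_cv` objects.
#' @return A ggplot.
#' @export
plot_rmse_comparison <- function(cv_specific, cv_neutral) {
  d <- dplyr::bind_rows(
    dplyr::mutate(cv_specific$per_repeat, model = "race-specific"),
    dplyr::mutate(cv_neutral$per_repeat, model = "race-neutral"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rmse, fill = .data$model,
                                  colour = .data$model)) +
    ggplot2::geom_density(alpha = 0.35) +
    ggplot2::scale_fill_manual(values = c("race-specific" = "#2166ac",
                                          "race-neutral" = "#1b7837")) +
    ggplot2::scale_colour_manual(values = c("race-specific" = "#2166ac",
                                            "race-neutral" = "#1b7837")) +
    ggplot2::labs(x = "held-out RMSE (L)", y = "density") +
    ggplot2::theme_minimal()
}

#' Null-distribution plot for a resampling test
#'
#' @param object A `spiro_resampling` object.
#' @param ... Unused.
#' @return A ggplot with the observed RMSE difference marked.
#' @method autoplot spiro_resampling
#' @export
autoplot.spiro_resampling <- function(object, ...) {
  d <- tibble::tibble(stat = object$null_rmse)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed[["rmse_diff"]],
                        colour = "#b2182b", linewidth = 1) +
    ggplot2::labs(x = "RMSE difference (L), resampled",
                  y = "count",
                  title = paste0(object$method, " distribution; p = ",
                                 signif(object$p_rmse, 3))) +
    ggplot2::theme_minimal()
}
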