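#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and summarize experiment reports
#'
#' `tidy()` returns the per-seed run table (one row per mode/strength,
#' dataset and seed); `glance()` returns the one-row-per-condition
#' summary (mean +/- sd accuracy over seeds, or the mean robustness
#' curve).
#'
#' @param x A `stainshift_report` from one of the `run_*_experiment()`
#'   functions.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.stainshift_report <- function(x, ...) {
  tibble::as_tibble(x$runs)
}

#' @rdname tidy.stainshift_report
#' @export
glance.stainshift_report <- function(x, ...) {
  tibble::as_tibble(x$summary)
}

#' Plot experiment reports
#'
#' `normalization_experiment` and `ensemble_experiment` reports plot
#' mean accuracy (+/- sd over paired seeds) per mode and dataset;
#' `artifact_experiment` reports plot the with/without-training-artifact
#' robustness curves against strength, faceted by dataset.
#'
#' @param object A `stainshift_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.normalization_experiment <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$mode, y = .data$mean_accuracy,
                                  fill = .data$dataset)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_accuracy - .data$sd_accuracy,
                   ymax = .data$mean_accuracy + .data$sd_accuracy),
      position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "tile accuracy",
                  title = "Color handling vs internal/external accuracy") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.normalization_experiment
#' @export
autoplot.ensemble_experiment <- function(object, ...) {
  s <- object$summary
  s$mode <- factor(s$mode, levels = c("single", "bagging", "noisy"))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$mode, y = .data$mean_accuracy,
                                  fill = .data$dataset)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_accuracy - .data$sd_accuracy,
                   ymax = .data$mean_accuracy + .data$sd_accuracy),
      position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "tile accuracy",
                  title = "Single model vs bagging vs NoisyEnsemble") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.normalization_experiment
#' @export
autoplot.artifact_experiment <- function(object, ...) {
  s <- tidyr::pivot_longer(object$summary,
                           cols = c("acc_with", "acc_without"),
                           names_to = "arm", values_to = "accuracy")
  s$arm <- ifelse(s$arm == "acc_with", "artifact in training",
                  "clean training")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$strength, y = .data$accuracy,
                                  color = .data$arm)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~dataset) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = sprintf("%s strength", object$meta$family),
                  y = "tile accuracy", color = NULL,
                  title = "Artifact robustness with/without training exposure") +
    ggplot2::theme_minimal()
}
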