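#' Plot a regularization path
#'
#' Cross-validation (and, when present, test) RMSE together with the
#' number of active sensors as a function of the penalty, on a log axis.
#'
#' @param object a [lambda_path()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.lambda_path <- function(object, ...) {
  df <- tibble::as_tibble(object)[, intersect(
    c("lambda", "cv_rmse", "test_rmse", "n_active"), names(object))]
  long <- tidyr::pivot_longer(df, -"lambda", names_to = "panel",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lambda, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = expression(lambda), y = NULL,
                  title = "Group-lasso regularization path")
}

#' Plot an accuracy-power trade-off curve
#'
#' @param object a [tradeoff_curve()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tradeoff_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$rmse_increase, y = .data$delta_pct)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "RMSE increase over optimum (bpm)",
                  y = "Current reduction (% of total)",
                  title = "Accuracy-power trade-off")
}

#' Plot per-cluster sensor dropout levels
#'
#' Bar chart of the largest penalty at which each sensor remains active,
#' with the CV-selected penalty as a horizontal reference: sensors whose
#' bar falls below the line are duty-cycled off.
#'
#' @param levels a [dropout_levels()] tibble (optionally with a `cluster`
#'   column when rows from several paths are bound together).
#' @param lambda_opt optional CV-selected penalty for the reference line.
#' @return A ggplot object.
#' @export
plot_dropout_levels <- function(levels, lambda_opt = NULL) {
  p <- ggplot2::ggplot(levels,
                       ggplot2::aes(x = .data$sensor, y = .data$lambda_level)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = expression(lambda ~ "dropout level"),
                  title = "Sensor dropout levels") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("cluster" %in% names(levels)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$cluster))
  }
  if (!is.null(lambda_opt)) {
    p <- p + ggplot2::geom_hline(yintercept = lambda_opt, linetype = "dashed")
  }
  p
}

#' Plot measured and predicted heart rate on the test day
#'
#' @param report a [run_pipeline()] result.
#' @return A ggplot object.
#' @export
plot_predictions <- function(report) {
  df <- tidyr::pivot_longer(report$predictions,
                            c("y", "clustered", "unclustered"),
                            names_to = "series", values_to = "bpm")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$bpm,
                                   colour = .data$series)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time (s)", y = "heart rate (bpm)", colour = NULL,
                  title = "Test-day heart-rate prediction")
}
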