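# ggplot2 methods for result objects.

#' Plot a power table
#'
#' Power (or another cell metric) as a function of centroid separation, one
#' line per sample size.
#'
#' @param object A `power_table` from [power_grid()].
#' @param metric One of `"power"`, `"k_accuracy"`, `"mean_accuracy"`,
#'   `"mean_silhouette"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_table <- function(object, metric = "power", ...) {
  stopifnot(metric %in% c("power", "k_accuracy", "mean_accuracy", "mean_silhouette"))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$delta, y = .data[[metric]],
                                       colour = factor(.data$n))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(Delta), y = metric, colour = "N",
                  title = sprintf("%s, k = %d (%s%%)",
                                  object$algorithm[1], object$k_true[1],
                                  object$weights[1])) +
    ggplot2::theme_minimal()
}

#' Plot a method comparison
#'
#' Power and cluster-number accuracy curves per method as a function of
#' centroid separation; for mixtures the BIC-based k selection is shown
#' dashed.
#'
#' @param object A `method_comparison` from [compare_methods()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.method_comparison <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("power", "k_accuracy"), names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$delta, y = .data$value,
                                     colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = expression(Delta), y = NULL,
                  title = sprintf("Matched comparison, true k = %d, N = %d",
                                  object$k_true[1], object$n[1])) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a (reduced) dataset
#'
#' First two feature columns coloured by the ground-truth subgroup when
#' available.
#'
#' @param data A dataset tibble (2+ feature columns, optional `.cluster`).
#' @return A ggplot object.
#' @export
plot_dataset <- function(data) {
  X <- feature_matrix(data)
  df <- tibble(x = X[, 1], y = X[, 2])
  lab <- truth_labels(data)
  p <- if (is.null(lab)) {
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y))
  } else {
    df$subgroup <- factor(lab)
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$subgroup))
  }
  p + ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = colnames(X)[1], y = colnames(X)[2]) +
    ggplot2::theme_minimal()
}
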