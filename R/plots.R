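#' QQ plot of TWAS chi-square statistics
#'
#' Plots observed `z^2` order statistics against theoretical 1-df
#' chi-square quantiles, per model; a calibrated null follows the
#' diagonal.
#'
#' @param results a results tibble (from [run_experiment()] or
#'   [tidy.twas_experiment()]) with columns `model` and `z_twas`.
#' @return A ggplot object.
#' @export
plot_twas_qq <- function(results) {
  df <- results |>
    dplyr::filter(is.finite(.data$z_twas)) |>
    dplyr::group_by(.data$model) |>
    dplyr::arrange(.data$z_twas^2, .by_group = TRUE) |>
    dplyr::mutate(
      observed = .data$z_twas^2,
      expected = qchisq(stats::ppoints(dplyr::n()), df = 1)
    ) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed,
                                   colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(
      x = expression("Expected" ~ chi^2), y = expression("Observed" ~ chi^2),
      colour = "model"
    ) +
    ggplot2::theme_minimal()
}

#' Power curves across a simulation grid
#'
#' Line plot of estimated power against a grid variable (typically
#' `h2ge`), one line per model.
#'
#' @param metrics a tibble with columns `model`, `power`, and the grid
#'   column named by `x` (e.g. stacked [twas_metrics()] reports with the
#'   grid value bound on).
#' @param x name of the grid column (default `"h2ge"`).
#' @return A ggplot object.
#' @export
plot_power_curve <- function(metrics, x = "h2ge") {
  ggplot2::ggplot(metrics, ggplot2::aes(.data[[x]], .data$power,
                                        colour = .data$model,
                                        group = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = x, y = "power", colour = "model") +
    ggplot2::theme_minimal()
}

#' @method autoplot twas_experiment
#' @export
autoplot.twas_experiment <- function(object, ...) {
  plot_twas_qq(object$results)
}
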