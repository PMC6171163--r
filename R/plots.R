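## ggplot2 display methods for curve and profile results.

#' Plot a power curve
#'
#' @param object A `repool_power_curve` tibble from [power_curve()].
#' @param ... Unused.
#' @return A ggplot object: power against odds ratio, one line per method.
#' @export
autoplot.repool_power_curve <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = exp(.data$log_or), y = .data$power,
                 colour = .data$method)
  ) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "odds ratio", y = "rejection probability", colour = "method",
      title = "Two-stage power by design",
      subtitle = sprintf("mean MAF %.3g", attr(object, "mean_maf"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a type-1 error profile
#'
#' @param object A `repool_error_profile` tibble from [type1_profile()].
#' @param ... Unused.
#' @return A ggplot object: false-positive rate (log scale) against the
#'   driving noncentrality, one line per method, facetted by scenario.
#' @export
autoplot.repool_error_profile <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$zeta, y = .data$rate, colour = .data$method)
  ) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(
      x = "driving noncentrality", y = "false-positive rate",
      colour = "method", title = "Type-1 error under cohort aberrance"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
plot.repool_power_curve <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.repool_error_profile <- function(x, ...) print(autoplot(x, ...))
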