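#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a replicate-averaged efficiency curve
#'
#' Mean normalized colony efficiency against the active fraction, with a
#' ribbon of plus/minus one between-replicate standard deviation and a red
#' dotted line marking the optimal active fraction.
#'
#' @param object An [aggregate_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot efficiency_curve
#' @export
autoplot.efficiency_curve <- function(object, ...) {
  opt <- optimal_active_fraction(object)
  ylab <- if (isTRUE(attr(object, "normalized"))) {
    "normalized colony efficiency"
  } else {
    "colony efficiency (unnormalized)"
  }
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$active_fraction,
                                    y = .data$mean_normalized_efficiency))
  if ("sd_normalized_efficiency" %in% names(object)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_normalized_efficiency - .data$sd_normalized_efficiency,
                   ymax = .data$mean_normalized_efficiency + .data$sd_normalized_efficiency),
      fill = "grey80")
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = opt, colour = "red", linetype = "dotted") +
    ggplot2::labs(
      x = "fraction of active workers", y = ylab,
      title = sprintf("%s, N = %s, beta = %g, delta = %g",
                      attr(object, "distribution")$kind %||% "",
                      attr(object, "n_workers") %||% "?",
                      object$beta[1], object$delta[1])) +
    ggplot2::theme_minimal()
}

#' Heat map of the optimal active fraction over (beta, delta)
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot with delta on the x axis, beta on the y axis and the
#'   optimal active fraction as fill.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$delta, y = .data$beta,
                               fill = .data$optimal_active_fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1),
                                  name = "optimal\nactive fraction") +
    ggplot2::labs(x = expression(delta), y = expression(beta),
                  title = sprintf("%s, N = %d, %s mode",
                                  object$config$distribution$kind,
                                  object$config$n_workers,
                                  object$config$mode)) +
    ggplot2::theme_minimal()
}

#' @export
plot.sweep_result <- function(x, ...) print(autoplot(x, ...))

#' Histogram of individual performances for one distribution
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws (default 1e5).
#' @param bins Histogram bins.
#' @return A ggplot.
#' @export
plot_performance_histogram <- function(spec, n = 1e5, bins = 50) {
  df <- sample_performances(spec, n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$performance)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "individual performance", y = "count",
                  title = spec$kind) +
    ggplot2::theme_minimal()
}
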