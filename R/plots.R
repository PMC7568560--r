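#' Plot the per-year network metric series
#'
#' One panel per metric (density, modularity, assortativity, median
#' PageRank, largest-component share) against the network year.
#'
#' @param metrics The tibble returned by [yearly_metrics()].
#' @return A ggplot object.
#' @export
plot_yearly_metrics <- function(metrics) {
  long <- metrics %>%
    select("year", "density", "modularity", "assortativity",
           "median_pagerank", "lcc_share") %>%
    tidyr::pivot_longer(-"year", names_to = "metric", values_to = "value") %>%
    filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Year", y = NULL,
                  title = "Cumulative co-authorship network metrics") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of cumulative author impact
#'
#' Histogram of log10 cumulative impact (zero-impact authors dropped);
#' on corpora like those this package models the log-transformed scores
#' are approximately normal.
#'
#' @param ledger An [impact_ledger()].
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_impact_distribution <- function(ledger, bins = 30) {
  totals <- cumulative_impact(ledger)
  totals <- totals[totals$impact > 0, ]
  ggplot2::ggplot(totals, ggplot2::aes(x = log10(.data$impact))) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            color = "white") +
    ggplot2::labs(x = "log10 cumulative impact", y = "Authors",
                  title = "Author impact distribution") +
    ggplot2::theme_minimal()
}

#' @describeIn gender_trend Plot the yearly proportions, the LOESS curve
#'   and the parity extrapolation line.
#' @param object A `gender_trend` object.
#' @param ... Unused.
#' @method autoplot gender_trend
#' @export
autoplot.gender_trend <- function(object, ...) {
  s <- object$series
  a <- coef(object$linear_fit)[[1]]
  b <- coef(object$linear_fit)[[2]]
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$proportion),
                        color = "grey40", size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed),
                       color = "steelblue", linewidth = 1) +
    ggplot2::geom_abline(intercept = a, slope = b, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "Year", y = "Proportion women",
                  title = "Gender trend and parity extrapolation") +
    ggplot2::theme_minimal()
  if (!is.na(object$parity_year)) {
    p <- p + ggplot2::geom_vline(xintercept = object$parity_year,
                                 linetype = "dotted", color = "firebrick")
  }
  p
}

#' @describeIn sensitivity_analysis Plot each variant's normalized final
#'   score distribution.
#' @param object A `sensitivity_result` object.
#' @param ... Unused.
#' @method autoplot sensitivity_result
#' @export
autoplot.sensitivity_result <- function(object, ...) {
  long <- purrr::map2(
    object$variants$variant, object$variants$scores,
    ~ mutate(.y, variant = .x)
  ) %>% bind_rows()
  long <- long[long$normalized > 0, ]
  ggplot2::ggplot(long, ggplot2::aes(x = log10(.data$normalized),
                                     color = .data$variant)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "log10 normalized impact", y = "Density",
                  title = "Sensitivity of the normalized score distribution") +
    ggplot2::theme_minimal()
}
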