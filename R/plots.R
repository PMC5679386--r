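#' Plot a one-way sensitivity sweep
#'
#' NMB of each strategy against the swept parameter value; the crossing
#' point, if any, is the preference threshold.
#'
#' @param object A `radcea_sweep` from [one_way_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radcea_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$value, y = .data$nmb,
                               colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = object$param_path[1], y = "Net monetary benefit (USD)",
                  colour = "Strategy") +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram
#'
#' Horizontal bars spanning each parameter's low/high NMB for the followed
#' strategy, widest spread on top.
#'
#' @param object A `radcea_tornado` from [tornado()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radcea_tornado <- function(object, ...) {
  df <- as_tibble(object)
  df$param_path <- factor(df$param_path, levels = rev(df$param_path))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$param_path)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$nmb_at_low,
                                       xend = .data$nmb_at_high,
                                       yend = .data$param_path),
                          linewidth = 5, colour = "steelblue") +
    ggplot2::labs(x = sprintf("NMB of %s (USD)", attr(object, "strategy")),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cohort state occupancy over time
#'
#' Stacked-area view of the fraction of the cohort in each health state per
#' annual cycle.
#'
#' @param object A `radcea_cohort` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radcea_cohort <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                               fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Cycle (years)", y = "Cohort fraction", fill = "State",
                  title = object$strategy) +
    ggplot2::theme_minimal()
}
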