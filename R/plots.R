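#' Plot an average-cost curve
#'
#' Draws the fixed-cost digression of the average cost per primary mission
#' against the yearly mission count, with maintenance-interval jumps
#' marked.
#'
#' @param object A `hems_curve` tibble from [average_cost_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hems_curve <- function(object, ...) {
  jumps <- filter(object, .data$jump)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$avg_total,
                                       colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = jumps, shape = 4, size = 1.5) +
    ggplot2::labs(x = "primary daytime missions x",
                  y = "average cost per primary mission (EUR)",
                  colour = "variation",
                  title = "Average-cost digression",
                  subtitle = "crosses: upward jumps at maintenance-interval crossings")
}
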