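#' Plot a signal trace
#'
#' @param object A [signal_trace()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signal_trace
#' @export
autoplot.signal_trace <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)",
                  y = paste0(trace_channel(object),
                             if (nzchar(trace_units(object)))
                               paste0(" (", trace_units(object), ")")
                             else "")) +
    ggplot2::theme_minimal()
}

#' Plot swing cycles over their source channel
#'
#' Shades every selected swing interval over the conditioned signal, the
#' standard visual check of a partition.
#'
#' @param cycles A `cycle_set` from [partition_with_hints()].
#' @param trace Optional [signal_trace()] to draw underneath.
#' @return A ggplot object.
#' @export
plot_cycles <- function(cycles, trace = NULL) {
  p <- ggplot2::ggplot()
  if (!is.null(trace)) {
    p <- p + ggplot2::geom_line(
      data = tibble::as_tibble(trace),
      ggplot2::aes(x = .data$time_s, y = .data$value), linewidth = 0.3)
  }
  p + ggplot2::geom_rect(
    data = tibble::as_tibble(cycles),
    ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                 ymin = -Inf, ymax = Inf),
    fill = "darkgreen", alpha = 0.2) +
    ggplot2::labs(x = "time (s)", y = "signal") +
    ggplot2::theme_minimal()
}

#' @rdname plot_cycles
#' @param object A `cycle_set`.
#' @param ... Unused.
#' @method autoplot cycle_set
#' @export
autoplot.cycle_set <- function(object, ...) plot_cycles(object)
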