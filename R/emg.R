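# Time-normalized per-cycle EMG activity curves.

#' Time-normalize an EMG envelope by gait cycle
#'
#' Slices the envelope at successive same-side foot contacts (the standard
#' gait-cycle anchor), resamples every cycle to 101 points spanning
#' 0-100% of the cycle by linear interpolation, and averages pointwise.
#' The per-cycle swing onset is the percentage of the cycle at which the
#' foot-off falls, so stance occupies `[0, swing_onset_pct)` and swing the
#' remainder.
#'
#' @param envelope A [signal_trace()], typically from [emg_envelope()].
#' @param events A [gait_events()] tibble containing at least two
#'   foot-contacts of `side` within the trace span.
#' @param side Side anchoring the cycles (default the single side present).
#' @return An object of class `gait_cycle_curves`: `curves` (long tibble
#'   `cycle`, `pct`, `value`), `mean_curve` (`pct`, `value`),
#'   `swing_onset_pct` (per cycle, `NA` if no foot-off inside),
#'   `n_cycles`.
#' @export
normalize_cycles <- function(envelope, events, side = NULL) {
  if (is.null(side)) {
    side <- unique(events$side)
    if (length(side) != 1) {
      stop("`side` required when events cover both sides", call. = FALSE)
    }
  }
  fc <- event_times(events, "foot_contact", side)
  fo <- event_times(events, "foot_off", side)
  t0 <- trace_t0(envelope)
  t1 <- t0 + trace_duration(envelope)
  fc <- fc[fc >= t0 - 1e-9 & fc <= t1 + 1e-9]
  if (length(fc) < 2) {
    stop("no complete gait cycle (need two same-side contacts inside the trace)",
         call. = FALSE)
  }
  pct <- seq(0, 100, length.out = 101L)
  rows <- list()
  onset <- numeric(0)
  for (i in seq_len(length(fc) - 1L)) {
    a <- fc[i]; b <- fc[i + 1L]
    grid <- seq(a, b, length.out = 101L)
    vals <- trace_at(envelope, grid)
    rows[[i]] <- tibble::tibble(cycle = i, pct = pct, value = vals)
    off <- fo[fo > a & fo < b]
    onset[i] <- if (length(off)) (off[1] - a) / (b - a) * 100 else NA_real_
  }
  curves <- dplyr::bind_rows(rows)
  mean_curve <- curves |>
    dplyr::group_by(.data$pct) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  out <- list(curves = curves, mean_curve = mean_curve,
              swing_onset_pct = onset, n_cycles = length(fc) - 1L,
              side = side, units = trace_units(envelope))
  class(out) <- "gait_cycle_curves"
  out
}

#' @export
print.gait_cycle_curves <- function(x, ...) {
  cat(sprintf(
    "<gait_cycle_curves> %d cycles (%s side), mean swing onset %.1f%% of cycle\n",
    x$n_cycles, x$side, mean(x$swing_onset_pct, na.rm = TRUE)))
  invisible(x)
}

#' @rdname tidy.gait_error_report
#' @method tidy gait_cycle_curves
#' @export
tidy.gait_cycle_curves <- function(x, ...) x$curves

#' Plot time-normalized EMG cycle curves
#'
#' One line per cycle, the pointwise mean emphasized, and the mean swing
#' phase shaded.
#'
#' @param object A `gait_cycle_curves` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gait_cycle_curves
#' @export
autoplot.gait_cycle_curves <- function(object, ...) {
  onset <- mean(object$swing_onset_pct, na.rm = TRUE)
  p <- ggplot2::ggplot(object$curves,
                       ggplot2::aes(x = .data$pct, y = .data$value,
                                    group = .data$cycle)) +
    ggplot2::geom_line(alpha = 0.35, colour = "grey40") +
    ggplot2::geom_line(data = object$mean_curve,
                       ggplot2::aes(group = NULL), linewidth = 1,
                       colour = "black") +
    ggplot2::labs(x = "% gait cycle", y = paste0("envelope",
                  if (nzchar(object$units)) paste0(" (", object$units, ")")
                  else "")) +
    ggplot2::theme_minimal()
  if (is.finite(onset)) {
    p <- p + ggplot2::annotate("rect", xmin = onset, xmax = 100,
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "darkgreen")
  }
  p
}

#' Export cycle curves as CSV (and optionally a plot)
#'
#' Writes a deterministic CSV with 101 rows: a `pct` column, one
#' `cycle_<i>` column per cycle, and a `mean` column. When `plot_path` is
#' given, an [autoplot.gait_cycle_curves()] figure is saved there too.
#'
#' @param curves A `gait_cycle_curves` object.
#' @param path Output CSV path.
#' @param plot_path Optional image path (`.png`/`.pdf`).
#' @return `path`, invisibly.
#' @export
export_cycle_plot <- function(curves, path, plot_path = NULL) {
  wide <- tidyr::pivot_wider(curves$curves, names_from = "cycle",
                             values_from = "value", names_prefix = "cycle_")
  wide$mean <- curves$mean_curve$value
  utils::write.csv(as.data.frame(wide), path, row.names = FALSE)
  if (!is.null(plot_path)) {
    ggplot2::ggsave(plot_path, autoplot.gait_cycle_curves(curves),
                    width = 7, height = 4, dpi = 150)
  }
  invisible(path)
}
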