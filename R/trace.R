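#' Construct a uniformly sampled signal trace
#'
#' A signal trace is the package's elementary container: one uniformly
#' sampled channel (accelerometer, vertical ground reaction force, EMG, or
#' one axis of a motion-capture marker) held as a tibble with columns
#' `time_s` and `value`, plus attributes recording the channel label,
#' sampling rate, time origin and physical units. The time of sample
#' `i` (0-based) is `t0_s + i / rate_hz`.
#'
#' @param values Numeric vector of samples. Must be finite: missing or
#'   non-finite samples are rejected rather than imputed, since no
#'   principled imputation rule exists for event-level gait analysis.
#' @param rate_hz Sampling rate in Hz (> 0).
#' @param t0_s Time of the first sample in seconds.
#' @param channel Channel label, e.g. `"acc_foot_r"`.
#' @param units Physical units label, e.g. `"m/s^2"`, `"N"`, `"mV"`, `"m"`.
#' @return A tibble of class `signal_trace` with columns `time_s`, `value`.
#' @examples
#' tr <- signal_trace(sin(2 * pi * 2 * seq(0, 5, by = 0.01)), rate_hz = 100)
#' trace_rate(tr)
#' @export
signal_trace <- function(values, rate_hz, t0_s = 0, channel = "signal",
                         units = "") {
  values <- as.numeric(values)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0) {
    stop("`rate_hz` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(t0_s) || length(t0_s) != 1L || !is.finite(t0_s)) {
    stop("`t0_s` must be a single finite number", call. = FALSE)
  }
  if (anyNA(values) || (length(values) && !all(is.finite(values)))) {
    bad <- which(!is.finite(values))[1L]
    stop(sprintf("non-finite sample at index %d of channel '%s'", bad, channel),
         call. = FALSE)
  }
  n <- length(values)
  out <- tibble::tibble(
    time_s = t0_s + (seq_len(n) - 1L) / rate_hz,
    value = values
  )
  structure(out,
            class = c("signal_trace", class(out)),
            channel = channel, rate_hz = rate_hz, t0_s = t0_s, units = units)
}

#' Trace accessors
#'
#' Small helpers reading the metadata attributes of a [signal_trace()].
#'
#' @param x A `signal_trace`.
#' @return `trace_rate()` the sampling rate in Hz; `trace_channel()` the
#'   channel label; `trace_units()` the units label; `trace_t0()` the time of
#'   the first sample (s); `trace_duration()` the spanned duration in
#'   seconds (`n / rate`).
#' @export
trace_rate <- function(x) attr(x, "rate_hz")

#' @rdname trace_rate
#' @export
trace_channel <- function(x) attr(x, "channel")

#' @rdname trace_rate
#' @export
trace_units <- function(x) attr(x, "units")

#' @rdname trace_rate
#' @export
trace_t0 <- function(x) attr(x, "t0_s")

#' @rdname trace_rate
#' @export
trace_duration <- function(x) nrow(x) / trace_rate(x)

# Rebuild a trace with new sample values, keeping all metadata.
trace_with_values <- function(x, values) {
  signal_trace(values, rate_hz = trace_rate(x), t0_s = trace_t0(x),
               channel = trace_channel(x), units = trace_units(x))
}

# Convert a time (s) to the nearest 0-based sample index, clamped to range.
time_to_index <- function(x, t) {
  i <- round((t - trace_t0(x)) * trace_rate(x))
  pmin(pmax(i, 0), nrow(x) - 1L)
}

# Extract the half-open sample window [start_s, end_s) as a numeric vector.
trace_window <- function(x, start_s, end_s) {
  i0 <- ceiling((start_s - trace_t0(x)) * trace_rate(x) - 1e-9)
  i1 <- ceiling((end_s - trace_t0(x)) * trace_rate(x) - 1e-9)
  i0 <- max(i0, 0)
  i1 <- min(i1, nrow(x))
  if (i1 <= i0) return(numeric(0))
  x$value[(i0 + 1L):i1]
}

# Linear interpolation of trace values at arbitrary times.
trace_at <- function(x, t) {
  stats::approx(x$time_s, x$value, xout = t, rule = 2)$y
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> channel '%s': %d samples @ %g Hz (%.3f s)%s\n",
              trace_channel(x), nrow(x), trace_rate(x), trace_duration(x),
              if (nzchar(trace_units(x))) paste0(" [", trace_units(x), "]")
              else ""))
  NextMethod()
}
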