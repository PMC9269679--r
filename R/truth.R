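# Force-plate ground truth and dual-stream synchronization.

#' Force-plate detection parameters
#'
#' @param threshold_n Vertical ground-reaction-force threshold in Newtons;
#'   default 10 N, the standard laboratory criterion for foot contact and
#'   foot off.
#' @param debounce_s Minimum dwell time a crossing must sustain to count
#'   (s); default 0.05. The 10 N rule alone chatters on noisy plates, so a
#'   crossing only registers when the signal stays on the new side of the
#'   threshold for at least this long.
#' @param rate_hz Expected plate sampling rate (Hz), default 1000.
#' @return A list of class `force_plate_spec`.
#' @export
force_plate_spec <- function(threshold_n = 10, debounce_s = 0.05,
                             rate_hz = 1000) {
  if (threshold_n <= 0) stop("`threshold_n` must be positive", call. = FALSE)
  if (debounce_s < 0) stop("`debounce_s` must be >= 0", call. = FALSE)
  structure(list(threshold_n = threshold_n, debounce_s = debounce_s,
                 rate_hz = rate_hz), class = "force_plate_spec")
}

#' Detect gait events from a vertical ground reaction force trace
#'
#' Foot contact is the first sample at or above the force threshold of an
#' upward crossing sustained at least `debounce_s`; foot off is the first
#' sample below the threshold of a sustained downward crossing. Crossing
#' times are reported at sample resolution (no interpolation). Events
#' alternate by construction of the two-state machine; a trace that starts
#' already loaded opens in stance without emitting a contact.
#'
#' @param grf A [signal_trace()] of vertical GRF in Newtons.
#' @param spec A [force_plate_spec()].
#' @param side Body side recorded on the events.
#' @return A [gait_events()] tibble (possibly empty for a quiet trace).
#' @export
detect_events_forceplate <- function(grf, spec = force_plate_spec(),
                                     side = c("right", "left")) {
  side <- match.arg(side)
  above <- grf$value >= spec$threshold_n
  nd <- max(1L, ceiling(spec$debounce_s * trace_rate(grf)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  contacts <- numeric(0); offs <- numeric(0)
  state <- NA   # unknown until the first sustained run
  for (i in seq_along(r$lengths)) {
    if (r$lengths[i] < nd) next   # debounce: too short to change state
    if (is.na(state)) {
      state <- r$values[i]        # opening state, no event emitted
      next
    }
    if (r$values[i] && !state) {
      contacts <- c(contacts, grf$time_s[starts[i]])
      state <- TRUE
    } else if (!r$values[i] && state) {
      offs <- c(offs, grf$time_s[starts[i]])
      state <- FALSE
    }
  }
  gait_events(foot_contacts_s = contacts, foot_offs_s = offs, side = side)
}

#' Estimate the time offset between two synchronously recorded streams
#'
#' Finds the lag maximizing the normalized cross-correlation of the two
#' (mean-removed) signals over lags within `max_lag_s`, then refines the
#' peak to sub-sample precision by parabolic interpolation. A positive
#' return value means `b` lags `a`: `b(t) ~ a(t - offset)`. With gait
#' signals this aligns the dominant per-step peaks of the two streams
#' simultaneously, which is deterministic where literal discrete peak
#' pairing is not.
#'
#' @param a,b [signal_trace()] objects; `b` is resampled onto `a`'s rate by
#'   linear interpolation if the rates differ.
#' @param max_lag_s Maximum |lag| searched (s).
#' @return Offset in seconds.
#' @export
synchronize_streams <- function(a, b, max_lag_s = 2) {
  rate <- trace_rate(a)
  va <- a$value - mean(a$value)
  vb <- if (abs(trace_rate(b) - rate) < 1e-9) b$value else {
    tt <- trace_t0(b) + (seq_len(ceiling(trace_duration(b) * rate)) - 1L) / rate
    trace_at(b, tt)
  }
  vb <- vb - mean(vb)
  if (stats::sd(va) < 1e-12 || stats::sd(vb) < 1e-12) {
    stop("cannot synchronize flat (zero-variance) signals", call. = FALSE)
  }
  L <- as.integer(round(max_lag_s * rate))
  lags <- (-L):L
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      n <- min(length(va), length(vb) - l)
      if (n < 2) return(-Inf)
      x <- va[1:n]; y <- vb[(1 + l):(l + n)]
    } else {
      n <- min(length(va) + l, length(vb))
      if (n < 2) return(-Inf)
      x <- va[(1 - l):(n - l)]; y <- vb[1:n]
    }
    sx <- stats::sd(x); sy <- stats::sd(y)
    if (sx < 1e-12 || sy < 1e-12) return(-Inf)
    mean((x - mean(x)) * (y - mean(y))) / (sx * sy)
  }, numeric(1))
  i <- which.max(cc)
  lag <- lags[i]
  # parabolic refinement around the discrete peak
  frac <- 0
  if (i > 1 && i < length(cc) && is.finite(cc[i - 1]) && is.finite(cc[i + 1])) {
    denom <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
    if (abs(denom) > 1e-15) frac <- 0.5 * (cc[i - 1] - cc[i + 1]) / denom
    frac <- max(min(frac, 0.5), -0.5)
  }
  (lag + frac) / rate
}
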