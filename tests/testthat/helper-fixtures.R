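# Shared fixtures and independent oracles, all built in code.

sine_trace <- function(freq_hz, rate_hz = 100, dur_s = 5, amp = 1,
                       channel = "sine") {
  t <- (seq_len(round(dur_s * rate_hz)) - 1) / rate_hz
  signal_trace(amp * sin(2 * pi * freq_hz * t), rate_hz, channel = channel)
}

rms <- function(x) sqrt(mean(x^2))

# Naive k-fold moving-average oracle: explicit per-sample loop with the
# same reflect-padding policy, independent of stats::filter.
naive_kz <- function(x, m, k) {
  h <- (m - 1) %/% 2
  y <- x
  for (j in seq_len(k)) {
    n <- length(y)
    yp <- c(y[(h + 1):2], y, y[(n - 1):(n - h)])
    y <- vapply(seq_len(n), function(i) mean(yp[i:(i + 2 * h)]), numeric(1))
  }
  y
}

# Naive windowed RMS oracle (reflect padding, odd window).
naive_windowed_rms <- function(x, w) {
  if (w %% 2 == 0) w <- w + 1
  h <- (w - 1) %/% 2
  n <- length(x)
  xp <- c(x[(h + 1):2], x, x[(n - 1):(n - h)])
  vapply(seq_len(n), function(i) sqrt(mean(xp[i:(i + 2 * h)]^2)), numeric(1))
}

# Exhaustive template-match oracle: explicit double loop over offsets and
# scales, its own resampling and per-symbol cost accumulation.
brute_force_match <- function(template, ct, params) {
  rate <- trace_rate(ct)
  q <- quantize(ct, params$levels)
  codes <- q$codes
  n <- length(codes)
  rows <- list()
  for (s in params$length_scales) {
    Ls <- max(2, round(template$length_s * s * rate))
    if (Ls > n) next
    tv <- stats::approx(seq(0, 1, length.out = length(template$values)),
                        template$values,
                        xout = seq(0, 1, length.out = Ls))$y
    tq <- quantize(tv, params$levels, bin_edges = q$bin_edges)$codes
    for (off in seq_len(n - Ls + 1)) {
      tot <- 0
      for (j in seq_len(Ls)) {
        d <- abs(codes[off + j - 1] - tq[j])
        tot <- tot + min(d, 2) / 2
      }
      dist <- tot / Ls
      if (dist < params$accept_threshold) {
        start_s <- trace_t0(ct) + (off - 1) / rate
        rows[[length(rows) + 1]] <- data.frame(
          start_s = start_s, end_s = start_s + Ls / rate,
          distance = dist, scale = s)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start_s = numeric(0), end_s = numeric(0),
               distance = numeric(0), scale = numeric(0))
  out[order(out$distance, out$start_s), , drop = FALSE]
}

# All subsets of candidate indices that remain feasible under refractory
# dilation (for checking the greedy selection policy on <= 8 candidates).
feasible_subsets <- function(cands, refractory_s) {
  n <- nrow(cands)
  ok <- list()
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    good <- TRUE
    if (length(idx) > 1) {
      for (a in idx) for (b in idx) {
        if (a < b &&
            cands$start_s[a] - refractory_s < cands$end_s[b] &&
            cands$end_s[a] + refractory_s > cands$start_s[b]) {
          good <- FALSE
        }
      }
    }
    if (good) ok[[length(ok) + 1]] <- idx
  }
  ok
}

# One standard synthetic recording, generated once per test run.
default_recording <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_recording(synthetic_gait_spec(n_steps = 20, seed = 1))
    }
    cache
  }
})

first_swing_hint <- function(rec, side = "right", channel = "acc_foot_r",
                             k = 2) {
  tr <- rec$truth_events
  fo <- sort(tr$time_s[tr$event_type == "foot_off" & tr$side == side])
  fc <- sort(tr$time_s[tr$event_type == "foot_contact" & tr$side == side])
  o <- fo[k]
  gait_hint(channel, o, fc[fc > o][1])
}
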