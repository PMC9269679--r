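#' Signal-conditioning parameters
#'
#' Collects the tunable parameters of the conditioning stages applied
#' before segmentation and template matching.
#'
#' @param kz_m Kolmogorov-Zurbenko window length in samples (odd, >= 1).
#'   Default 5 at 100 Hz: short enough to keep the ~0.4 s swing-phase
#'   transients, long enough to kill sample-level noise.
#' @param kz_k Number of KZ iterations (>= 1), default 3.
#' @param fft_cutoff_hz Low-pass cutoff of the FFT smoother (Hz), default
#'   15: gait accelerometer content lives below ~10 Hz.
#' @param emg_band_hz Two-element band edges for the EMG band-pass (Hz),
#'   default `c(20, 450)`.
#' @param emg_order Butterworth order, default 4.
#' @param envelope_cutoff_hz Low-pass cutoff of the rectified-EMG envelope
#'   (Hz), default 10.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(kz_m = 5L, kz_k = 3L, fft_cutoff_hz = 15,
                        emg_band_hz = c(20, 450), emg_order = 4L,
                        envelope_cutoff_hz = 10) {
  # NULL disables a stage entirely
  if (!is.null(kz_m) && kz_m %% 2 == 0) {
    stop("KZ window `kz_m` must be odd", call. = FALSE)
  }
  if (!is.null(kz_m) && kz_k < 1) stop("`kz_k` must be >= 1", call. = FALSE)
  if (length(emg_band_hz) != 2 || emg_band_hz[1] <= 0 ||
      emg_band_hz[2] <= emg_band_hz[1]) {
    stop("`emg_band_hz` must be ascending positive band edges", call. = FALSE)
  }
  structure(list(kz_m = if (!is.null(kz_m)) as.integer(kz_m),
                 kz_k = if (!is.null(kz_k)) as.integer(kz_k),
                 fft_cutoff_hz = fft_cutoff_hz, emg_band_hz = emg_band_hz,
                 emg_order = as.integer(emg_order),
                 envelope_cutoff_hz = envelope_cutoff_hz),
            class = "filter_spec")
}

# Reflect-pad a vector by h samples on each side (no repeated edge sample).
pad_reflect <- function(x, h) {
  n <- length(x)
  if (h == 0) return(x)
  if (h >= n) stop("reflect pad longer than signal", call. = FALSE)
  c(x[(h + 1):2], x, x[(n - 1):(n - h)])
}

#' Kolmogorov-Zurbenko filter
#'
#' The KZ filter is `k` iterated applications of a centred moving average of
#' odd window length `m`; its effective kernel is the `k`-fold convolution
#' of a length-`m` boxcar. Edges are handled by reflect-padding at every
#' iteration so endpoints are not dragged toward zero (endpoint droop would
#' bias the first and last detected event times).
#'
#' @param x A [signal_trace()] or numeric vector.
#' @param m Window length in samples (odd, `m <= length(x)`).
#' @param k Number of iterations (>= 1).
#' @return Smoothed object of the same type and length as the input.
#' @examples
#' kz_filter(c(0, 0, 1, 0, 0), m = 3, k = 2)  # kernel (1,2,3,2,1)/9
#' @export
kz_filter <- function(x, m = 5L, k = 3L) {
  vals <- if (inherits(x, "signal_trace")) x$value else as.numeric(x)
  m <- as.integer(m); k <- as.integer(k)
  if (m %% 2 == 0) stop("KZ window `m` must be odd", call. = FALSE)
  if (m > length(vals)) stop("KZ window longer than signal", call. = FALSE)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  h <- (m - 1L) %/% 2L
  y <- vals
  for (i in seq_len(k)) {
    if (h > 0) {
      yp <- pad_reflect(y, h)
      y <- as.numeric(stats::filter(yp, rep(1 / m, m), sides = 2))
      y <- y[(h + 1):(h + length(vals))]
    }
  }
  if (inherits(x, "signal_trace")) trace_with_values(x, y) else y
}

#' FFT low-pass smoothing
#'
#' Hard low-pass in the frequency domain: the discrete Fourier transform is
#' taken, every bin with |frequency| above `cutoff_hz` is zeroed, and the
#' signal is inverse-transformed. Length-preserving, zero-phase and
#' idempotent (smoothing twice equals smoothing once).
#'
#' @param x A [signal_trace()], or numeric vector with `rate_hz` supplied.
#' @param cutoff_hz Cutoff frequency, `0 < cutoff_hz < rate/2`.
#' @param rate_hz Sampling rate, required when `x` is a bare vector.
#' @return Smoothed object of the same type and length as the input.
#' @export
fft_smooth <- function(x, cutoff_hz, rate_hz = NULL) {
  if (inherits(x, "signal_trace")) {
    rate_hz <- trace_rate(x)
    vals <- x$value
  } else {
    if (is.null(rate_hz)) stop("`rate_hz` required for bare vectors",
                               call. = FALSE)
    vals <- as.numeric(x)
  }
  if (cutoff_hz <= 0 || cutoff_hz >= rate_hz / 2) {
    stop(sprintf("cutoff %g Hz outside (0, %g)", cutoff_hz, rate_hz / 2),
         call. = FALSE)
  }
  n <- length(vals)
  if (n < 2) {
    return(if (inherits(x, "signal_trace")) x else vals)
  }
  sp <- stats::fft(vals)
  k <- 0:(n - 1)
  freq <- ifelse(k <= n / 2, k, k - n) * rate_hz / n
  sp[abs(freq) > cutoff_hz] <- 0
  y <- Re(stats::fft(sp, inverse = TRUE)) / n
  if (inherits(x, "signal_trace")) trace_with_values(x, y) else y
}

butter_filtfilt <- function(vals, rate_hz, w, type, order) {
  if (length(vals) <= 3 * (2 * order + 1)) {
    stop("trace shorter than filter warm-up length", call. = FALSE)
  }
  flt <- signal::butter(order, w, type = type)
  signal::filtfilt(flt, vals)
}

#' EMG band-pass filter
#'
#' Zero-phase (forward-backward) Butterworth band-pass of surface EMG,
#' default 20-450 Hz at order 4. Forward-backward application squares the
#' magnitude response and cancels phase lag, so burst timing is not shifted
#' relative to the gait events it is later partitioned by. When the
#' sampling rate is too low to carry the upper band edge, the edge is
#' clipped to 0.45 x rate with a warning.
#'
#' @param x A [signal_trace()] of raw EMG, or numeric vector with `rate_hz`.
#' @param spec A [filter_spec()].
#' @param rate_hz Sampling rate for bare vectors.
#' @return Band-passed object of the same type and length.
#' @export
emg_bandpass <- function(x, spec = filter_spec(), rate_hz = NULL) {
  if (inherits(x, "signal_trace")) {
    rate_hz <- trace_rate(x)
    vals <- x$value
  } else {
    if (is.null(rate_hz)) stop("`rate_hz` required for bare vectors",
                               call. = FALSE)
    vals <- as.numeric(x)
  }
  band <- spec$emg_band_hz
  nyq <- rate_hz / 2
  if (band[2] >= nyq) {
    band[2] <- 0.45 * rate_hz
    warning(sprintf("EMG upper band edge clipped to %.0f Hz for a %g Hz trace",
                    band[2], rate_hz), call. = FALSE)
  }
  y <- butter_filtfilt(vals, rate_hz, band / nyq, "pass", spec$emg_order)
  if (inherits(x, "signal_trace")) trace_with_values(x, y) else y
}

#' EMG linear envelope
#'
#' The standard linear envelope: full-wave rectification of the band-passed
#' EMG followed by a zero-phase fourth-order Butterworth low-pass at 10 Hz.
#' For a constant-amplitude sinusoidal burst of amplitude A the plateau
#' settles at the rectified mean 2A/pi.
#'
#' @inheritParams emg_bandpass
#' @return Envelope object of the same type and length; non-negative up to
#'   filter ringing.
#' @export
emg_envelope <- function(x, spec = filter_spec(), rate_hz = NULL) {
  if (inherits(x, "signal_trace")) {
    rate_hz <- trace_rate(x)
    vals <- x$value
  } else {
    if (is.null(rate_hz)) stop("`rate_hz` required for bare vectors",
                               call. = FALSE)
    vals <- as.numeric(x)
  }
  y <- butter_filtfilt(abs(vals), rate_hz,
                       spec$envelope_cutoff_hz / (rate_hz / 2), "low",
                       spec$emg_order)
  if (inherits(x, "signal_trace")) trace_with_values(x, y) else y
}

#' Condition an accelerometer channel for matching
#'
#' The conditioning applied before unsupervised segmentation and template
#' matching: FFT low-pass smoothing followed by the KZ filter. Either stage
#' can be disabled by setting its parameter to `NULL`/1.
#'
#' @param x A [signal_trace()].
#' @param spec A [filter_spec()].
#' @return Conditioned `signal_trace`.
#' @export
condition_trace <- function(x, spec = filter_spec()) {
  y <- x
  if (!is.null(spec$fft_cutoff_hz) && spec$fft_cutoff_hz < trace_rate(x) / 2) {
    y <- fft_smooth(y, spec$fft_cutoff_hz)
  }
  if (!is.null(spec$kz_m) && spec$kz_m > 1) {
    y <- kz_filter(y, spec$kz_m, spec$kz_k)
  }
  y
}
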