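# Synthetic multimodal gait recordings with exact ground-truth events.
#
# The generator emulates the measurement channels of a laboratory gait
# trial — foot accelerometer, per-foot vertical GRF, malleolus and pelvis
# markers, gastrocnemius-like EMG — around a commanded event timeline, so
# every downstream computation can be validated against known truth.

#' Specification of a synthetic gait recording
#'
#' @param n_steps Steps per side (>= 0). Each side gets `n_steps`
#'   foot-contacts; full swing phases number `n_steps` per side.
#' @param cadence_hz Steps per second per side, i.e. 1/cycle duration.
#' @param stance_fraction Stance share of the gait cycle, in (0, 1);
#'   0.60 is typical of healthy adult gait.
#' @param step_length_m Commanded step length: the inter-malleolus distance
#'   at every foot contact.
#' @param walking_speed_mps Commanded pelvis speed; defaults to the value
#'   implied by the step geometry, `2 * step_length_m * cadence_hz`.
#' @param noise_sd Accelerometer noise standard deviation (m/s^2).
#' @param step_time_cv Coefficient of variation of cycle durations
#'   (multiplicative Gaussian jitter, clipped at 3 sigma).
#' @param emg_burst_gain EMG burst amplitude scale (mV).
#' @param seed Integer RNG seed; part of the spec so recordings are
#'   bit-reproducible.
#' @return A list of class `synthetic_gait_spec`.
#' @export
synthetic_gait_spec <- function(n_steps = 20L, cadence_hz = 1.0,
                                stance_fraction = 0.60, step_length_m = 0.45,
                                walking_speed_mps = NULL, noise_sd = 0.5,
                                step_time_cv = 0.03, emg_burst_gain = 1.0,
                                seed = 1L) {
  if (stance_fraction <= 0 || stance_fraction >= 1) {
    stop("`stance_fraction` must lie in (0, 1)", call. = FALSE)
  }
  if (n_steps < 0) stop("`n_steps` must be >= 0", call. = FALSE)
  if (noise_sd < 0 || step_time_cv < 0) {
    stop("`noise_sd` and `step_time_cv` must be >= 0", call. = FALSE)
  }
  if (step_time_cv > 0.25) {
    stop("`step_time_cv` > 0.25 makes stance + swing exceed the cycle for some steps",
         call. = FALSE)
  }
  if (is.null(walking_speed_mps)) {
    walking_speed_mps <- 2 * step_length_m * cadence_hz
  }
  structure(list(n_steps = as.integer(n_steps), cadence_hz = cadence_hz,
                 stance_fraction = stance_fraction,
                 step_length_m = step_length_m,
                 walking_speed_mps = walking_speed_mps, noise_sd = noise_sd,
                 step_time_cv = step_time_cv,
                 emg_burst_gain = emg_burst_gain, seed = as.integer(seed)),
            class = "synthetic_gait_spec")
}

# Double-bump body-weight curve over normalized stance phase u in [0, 1);
# stays >= 0 and tapers to 0 at both ends.
grf_shape <- function(u) {
  sin(pi * u)^0.7 * (1 - 0.3 * exp(-((u - 0.5) / 0.18)^2))
}

# Fill a 1000 Hz force vector over loaded interval [a, b) with a curve
# that is >= floor_n throughout (so threshold crossings land exactly at
# the interval bounds). shape: "bump", "fade_out" (initial stance),
# "fade_in" (final stance).
fill_grf <- function(F, t, a, b, bw, floor_n, shape) {
  idx <- which(t >= a - 1e-12 & t < b - 1e-12)
  if (!length(idx)) return(F)
  u <- (t[idx] - a) / (b - a)
  g <- switch(shape,
              bump = grf_shape(u),
              fade_out = cos(pi * u / 2),
              fade_in = sin(pi * u / 2))
  F[idx] <- floor_n + (bw - floor_n) * g
  F
}

#' Generate a synthetic multimodal gait recording
#'
#' Produces a [gait_recording()] whose channels are mutually consistent
#' with an exactly known event timeline:
#'
#' * `acc_foot_r` (100 Hz): quiet stance baseline plus, in every swing, a
#'   biphasic burst — a push-off transient near swing onset and a larger
#'   opposite-signed heel-strike transient near landing (amplitude ratio
#'   2:3) — with additive Gaussian noise.
#' * `grf_r` / `grf_l` (1000 Hz): zero during swing; during stance a
#'   double-bump body-weight curve that stays above the 10 N threshold, so
#'   threshold crossings land on the commanded events to within one sample.
#' * `ank_r_*`, `ank_l_*`, `asis_*` (100 Hz): malleolus markers advancing
#'   one stride per cycle such that the inter-malleolus distance at every
#'   contact equals the commanded step length; the pelvis marker advances
#'   at the commanded speed.
#' * `emg_gas_r` (1000 Hz): band-limited noise bursts gated to late stance
#'   (gastrocnemius push-off timing).
#'
#' `truth_events` records the exact commanded contact/off times for both
#' sides. Each side's timeline opens with a lead swing (a foot-off before
#' the first contact) and closes in stance, so the recording holds exactly
#' `n_steps` complete swing phases per side.
#'
#' @param spec A [synthetic_gait_spec()].
#' @return A [gait_recording()] with `truth_events`.
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "synthetic_gait_spec"))
  n <- spec$n_steps
  f <- spec$stance_fraction
  T0 <- 1 / spec$cadence_hz
  lead_in <- 1.5
  rate_lo <- 100; rate_hi <- 1000
  bw <- 650   # body weight, N
  with_local_seed(spec$seed, {
    if (n == 0) {
      t_end <- 3
      mk <- function(v, rate, ch, un) signal_trace(v, rate, 0, ch, un)
      n_lo <- round(t_end * rate_lo); n_hi <- round(t_end * rate_hi)
      traces <- list(
        acc_foot_r = mk(stats::rnorm(n_lo, 0, spec$noise_sd), rate_lo,
                        "acc_foot_r", "m/s^2"),
        grf_r = mk(rep(0, n_hi), rate_hi, "grf_r", "N"),
        grf_l = mk(rep(0, n_hi), rate_hi, "grf_l", "N"),
        emg_gas_r = mk(stats::rnorm(n_hi, 0, 0.01), rate_hi, "emg_gas_r", "mV"))
      for (ch in c("ank_r", "ank_l", "asis")) {
        for (ax in c("x", "y", "z")) {
          traces[[paste0(ch, "_", ax)]] <-
            mk(rep(if (ax == "z") 0.08 else 0, n_lo), rate_lo,
               paste0(ch, "_", ax), "m")
        }
      }
      return(gait_recording(traces, side = "both",
                            subject_id = sprintf("synth_seed%d", spec$seed),
                            truth_events = gait_events()))
    }
    # cycle durations (shared by both sides so the half-cycle interleaving
    # of left and right never drifts apart)
    mult <- 1 + spec$step_time_cv * stats::rnorm(n + 1)
    mult <- pmin(pmax(mult, 1 - 3 * spec$step_time_cv),
                 1 + 3 * spec$step_time_cv)
    Tc <- T0 * mult                       # Tc[1] paces the lead swing
    rc <- lead_in + c(0, cumsum(Tc[2:(n + 1)]))[1:n]   # right contacts
    ro <- c(rc[1] - (1 - f) * Tc[1],                   # right offs
            if (n > 1) rc[1:(n - 1)] + f * Tc[2:n])
    lc <- rc - Tc[1:n] / 2                             # left contacts
    lo <- c(lc[1] - (1 - f) * Tc[1],
            if (n > 1) lc[1:(n - 1)] + f * Tc[2:n])
    if (lo[1] <= 0.05) {
      stop("infeasible spec: lead swing starts before the recording does",
           call. = FALSE)
    }
    t_end <- rc[n] + 1.5
    t_lo <- (seq_len(round(t_end * rate_lo)) - 1L) / rate_lo
    t_hi <- (seq_len(round(t_end * rate_hi)) - 1L) / rate_hi

    # --- accelerometer: biphasic swing bursts (push-off 2 : heel-strike 3)
    acc <- stats::rnorm(length(t_lo), 0, spec$noise_sd)
    for (i in seq_len(n)) {
      a <- ro[i]; b <- rc[i]; W <- b - a
      u <- (t_lo - a) / W
      inw <- u >= 0 & u <= 1
      acc[inw] <- acc[inw] + 2.0 * sin(pi * u[inw])
      acc <- acc + 8 * exp(-((t_lo - (a + 0.18 * W)) / (0.07 * W))^2) -
        12 * exp(-((t_lo - (b - 0.12 * W)) / (0.05 * W))^2)
    }

    # --- ground reaction forces
    grf_r <- rep(0, length(t_hi)); grf_l <- rep(0, length(t_hi))
    grf_r <- fill_grf(grf_r, t_hi, 0, ro[1], bw, 15, "fade_out")
    grf_l <- fill_grf(grf_l, t_hi, 0, lo[1], bw, 15, "fade_out")
    for (i in seq_len(n - 1)) {
      grf_r <- fill_grf(grf_r, t_hi, rc[i], ro[i + 1], bw, 15, "bump")
      grf_l <- fill_grf(grf_l, t_hi, lc[i], lo[i + 1], bw, 15, "bump")
    }
    grf_r <- fill_grf(grf_r, t_hi, rc[n], t_end, bw, 15, "fade_in")
    grf_l <- fill_grf(grf_l, t_hi, lc[n], t_end, bw, 15, "fade_in")

    # --- markers: both feet start level; each landing advances one stride
    step <- spec$step_length_m
    stride <- 2 * step
    x0 <- 0.5
    foot_ap <- function(contacts, offs, land_pos, start_pos) {
      x <- rep(start_pos, length(t_lo))
      z <- rep(0.08, length(t_lo))
      from <- c(start_pos, land_pos[-length(land_pos)])
      for (i in seq_along(contacts)) {
        sw <- t_lo >= offs[i] & t_lo < contacts[i]
        u <- (t_lo[sw] - offs[i]) / (contacts[i] - offs[i])
        x[sw] <- from[i] + (land_pos[i] - from[i]) * 0.5 * (1 - cos(pi * u))
        z[sw] <- 0.08 + 0.07 * sin(pi * u)
        x[t_lo >= contacts[i]] <- land_pos[i]
      }
      list(x = x, z = z)
    }
    right <- foot_ap(rc, ro, x0 + seq_len(n) * stride, x0)
    left <- foot_ap(lc, lo, x0 + seq_len(n) * stride - step, x0)
    mknoise <- function(v) v + stats::rnorm(length(v), 0, 0.002)
    asis_x <- 0.2 + spec$walking_speed_mps * t_lo +
      0.005 * sin(2 * pi * spec$cadence_hz * t_lo)
    asis_z <- 0.95 + 0.008 * sin(4 * pi * spec$cadence_hz * t_lo)

    # --- EMG: late-stance gastrocnemius bursts (right side)
    gate <- rep(0, length(t_hi))
    r_st_start <- c(0, rc[seq_len(n - 1)])
    r_st_end <- c(ro, t_end)[seq_len(n)]
    for (i in seq_len(n)) {
      S <- r_st_end[i] - r_st_start[i]
      gate <- gate + exp(-((t_hi - (r_st_start[i] + 0.75 * S)) /
                             (0.10 * S))^2)
    }
    emg <- stats::rnorm(length(t_hi)) *
      (0.01 + 0.5 * spec$emg_burst_gain * gate)

    truth <- as_gait_events(dplyr::bind_rows(
      gait_events(rc, ro, side = "right"),
      gait_events(lc, lo, side = "left")))
    traces <- list(
      acc_foot_r = signal_trace(acc, rate_lo, 0, "acc_foot_r", "m/s^2"),
      grf_r = signal_trace(grf_r, rate_hi, 0, "grf_r", "N"),
      grf_l = signal_trace(grf_l, rate_hi, 0, "grf_l", "N"),
      emg_gas_r = signal_trace(emg, rate_hi, 0, "emg_gas_r", "mV"),
      ank_r_x = signal_trace(mknoise(right$x), rate_lo, 0, "ank_r_x", "m"),
      ank_r_y = signal_trace(mknoise(rep(0, length(t_lo))), rate_lo, 0,
                             "ank_r_y", "m"),
      ank_r_z = signal_trace(mknoise(right$z), rate_lo, 0, "ank_r_z", "m"),
      ank_l_x = signal_trace(mknoise(left$x), rate_lo, 0, "ank_l_x", "m"),
      ank_l_y = signal_trace(mknoise(rep(0, length(t_lo))), rate_lo, 0,
                             "ank_l_y", "m"),
      ank_l_z = signal_trace(mknoise(left$z), rate_lo, 0, "ank_l_z", "m"),
      asis_x = signal_trace(mknoise(asis_x), rate_lo, 0, "asis_x", "m"),
      asis_y = signal_trace(mknoise(rep(0, length(t_lo))), rate_lo, 0,
                            "asis_y", "m"),
      asis_z = signal_trace(mknoise(asis_z), rate_lo, 0, "asis_z", "m"))
    gait_recording(traces, side = "both",
                   subject_id = sprintf("synth_seed%d", spec$seed),
                   truth_events = truth)
  })
}

#' Generate a cohort of synthetic subjects
#'
#' Draws one [synthetic_gait_spec()] per subject, each parameter uniform
#' over its supplied range, and generates the recordings. Deterministic
#' given `seed`: the cohort seed drives the parameter draws, and subject
#' `i` records with seed `seed * 1000 + i`.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param ranges Named list of 2-element `c(min, max)` ranges for any of
#'   `cadence_hz`, `stance_fraction`, `step_length_m`, `noise_sd`,
#'   `step_time_cv`; a degenerate range fixes the parameter.
#' @param n_steps Steps per side for every subject.
#' @param seed Cohort seed.
#' @return Named list of [gait_recording()] objects; the drawn specs ride
#'   along as `attr(, "specs")`.
#' @export
generate_cohort <- function(n_subjects, ranges = list(), n_steps = 20L,
                            seed = 1L) {
  if (n_subjects < 1) stop("`n_subjects` must be >= 1", call. = FALSE)
  defaults <- list(cadence_hz = c(0.7, 1.2), stance_fraction = c(0.55, 0.65),
                   step_length_m = c(0.30, 0.55), noise_sd = c(0.5, 0.5),
                   step_time_cv = c(0.03, 0.03))
  bad <- setdiff(names(ranges), names(defaults))
  if (length(bad)) stop("unknown range(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  rng <- utils::modifyList(defaults, ranges)
  for (nm in names(rng)) {
    if (length(rng[[nm]]) != 2 || rng[[nm]][2] < rng[[nm]][1]) {
      stop("range for ", nm, " must be c(min, max)", call. = FALSE)
    }
  }
  specs <- with_local_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      draw <- function(nm) stats::runif(1, rng[[nm]][1], rng[[nm]][2])
      synthetic_gait_spec(
        n_steps = n_steps, cadence_hz = draw("cadence_hz"),
        stance_fraction = draw("stance_fraction"),
        step_length_m = draw("step_length_m"), noise_sd = draw("noise_sd"),
        step_time_cv = draw("step_time_cv"), seed = seed * 1000L + i)
    })
  })
  recs <- lapply(specs, generate_recording)
  names(recs) <- sprintf("subject_%02d", seq_len(n_subjects))
  attr(recs, "specs") <- specs
  recs
}
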