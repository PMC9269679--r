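# Spatio-temporal gait parameters: step length, gait speed, step counting,
# and the per-condition cohort summaries.

#' Assemble a 3D marker tibble from a recording
#'
#' Collects the `<prefix>_x`, `<prefix>_y`, `<prefix>_z` channels of a
#' recording into one tibble of 3D positions.
#'
#' @param rec A [gait_recording()].
#' @param prefix Marker channel prefix, e.g. `"ank_r"` or `"asis"`.
#' @return A tibble with columns `time_s`, `x`, `y`, `z`.
#' @export
marker_xyz <- function(rec, prefix) {
  chans <- paste0(prefix, "_", c("x", "y", "z"))
  miss <- setdiff(chans, names(rec$traces))
  if (length(miss)) {
    stop("marker channel(s) missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tx <- rec$traces[[chans[1]]]
  tibble::tibble(time_s = tx$time_s, x = tx$value,
                 y = rec$traces[[chans[2]]]$value,
                 z = rec$traces[[chans[3]]]$value)
}

marker_at <- function(m, t) {
  c(x = stats::approx(m$time_s, m$x, t, rule = 2)$y,
    y = stats::approx(m$time_s, m$y, t, rule = 2)$y,
    z = stats::approx(m$time_s, m$z, t, rule = 2)$y)
}

#' Per-step step lengths from malleolus markers
#'
#' At each foot-contact the Euclidean distance between the left and right
#' lateral malleolus markers is that side's step length: contact is the
#' moment of maximum step length.
#'
#' @param ankle_left,ankle_right Marker tibbles (`time_s`, `x`, `y`, `z`)
#'   sharing a time base, e.g. from [marker_xyz()].
#' @param events A [gait_events()] tibble; each side's contacts yield that
#'   side's step lengths.
#' @return A tibble with columns `side`, `time_s`, `step_length_m`.
#' @export
step_lengths <- function(ankle_left, ankle_right, events) {
  span <- range(ankle_left$time_s)
  rows <- list()
  for (s in unique(events$side)) {
    fc <- event_times(events, "foot_contact", s)
    bad <- fc[fc < span[1] - 1e-9 | fc > span[2] + 1e-9]
    if (length(bad)) {
      stop(sprintf("contact at %.3f s outside marker span [%.3f, %.3f]",
                   bad[1], span[1], span[2]), call. = FALSE)
    }
    if (!length(fc)) next
    d <- vapply(fc, function(t) {
      sqrt(sum((marker_at(ankle_left, t) - marker_at(ankle_right, t))^2))
    }, numeric(1))
    rows[[length(rows) + 1L]] <- tibble::tibble(side = s, time_s = fc,
                                                step_length_m = d)
  }
  if (!length(rows)) {
    return(tibble::tibble(side = character(0), time_s = numeric(0),
                          step_length_m = numeric(0)))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$time_s)
}

#' Gait speed from the pelvis marker
#'
#' Net straight-line displacement of the anterior superior iliac spine
#' marker between the first and last sample, divided by the elapsed time.
#' Net displacement (rather than path length) is insensitive to marker
#' jitter and matches straight-walkway trials.
#'
#' @param asis Marker tibble (`time_s`, `x`, `y`, `z`).
#' @return Speed in m/s.
#' @export
gait_speed <- function(asis) {
  n <- nrow(asis)
  if (n < 2) stop("marker trace has zero duration", call. = FALSE)
  dt <- asis$time_s[n] - asis$time_s[1]
  if (dt <= 0) stop("marker trace has zero duration", call. = FALSE)
  disp <- sqrt((asis$x[n] - asis$x[1])^2 + (asis$y[n] - asis$y[1])^2 +
                 (asis$z[n] - asis$z[1])^2)
  disp / dt
}

# Local maxima of v with prominence and separation constraints.
# Prominence of a peak: height above the higher of the two minima between
# the peak and the nearest strictly higher sample on each side. A side with
# no higher sample (the peak "sees" past the signal edge) is ignored, so a
# step plateau touching the start or end of a trial keeps its prominence;
# with both sides open the base is the global minimum.
peaks_with_prominence <- function(v, t, min_prom, min_sep_s) {
  n <- length(v)
  if (n < 3) return(integer(0))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    lhs <- which(v[seq_len(i - 1)] > v[i])
    lmin <- if (length(lhs) && max(lhs) < i - 1) {
      min(v[(max(lhs) + 1):(i - 1)])
    } else if (length(lhs)) v[i] else NA_real_
    rhs <- which(v[(i + 1):n] > v[i])
    rmin <- if (length(rhs)) {
      j <- i + min(rhs)
      if (j - 1 >= i + 1) min(v[(i + 1):(j - 1)]) else v[i]
    } else NA_real_
    base <- if (is.na(lmin) && is.na(rmin)) min(v) else
      max(lmin, rmin, na.rm = TRUE)
    v[i] - base
  }, numeric(1))
  keep <- cand[prom >= min_prom]
  if (!length(keep)) return(integer(0))
  # greedy separation, highest peaks first
  keep <- keep[order(v[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in keep) {
    if (!length(sel) || all(abs(t[i] - t[sel]) >= min_sep_s)) {
      sel <- c(sel, i)
    }
  }
  sort(sel)
}

#' Count steps from the left-right ankle distance signal
#'
#' The anterior-posterior left-minus-right ankle distance oscillates once
#' per step: every prominent local maximum (left foot ahead) and minimum
#' (right foot ahead) is one step. Peaks must exceed a prominence floor
#' (default 0.2 x the inter-quartile range of the distance signal) and be
#' separated by at least `min_sep_s` (default 0.3 s, faster than any
#' clinical step rate).
#'
#' @param ankle_ap_left,ankle_ap_right [signal_trace()] objects of the
#'   anterior-posterior ankle marker coordinate on a shared time base
#'   (`ankle_ap_right` is interpolated onto the left trace's grid if
#'   needed).
#' @param min_prom_frac Prominence floor as a fraction of IQR.
#' @param min_sep_s Minimum peak separation (s).
#' @return Integer step count (maxima + minima).
#' @export
count_steps <- function(ankle_ap_left, ankle_ap_right, min_prom_frac = 0.2,
                        min_sep_s = 0.3) {
  t <- ankle_ap_left$time_s
  d <- ankle_ap_left$value - trace_at(ankle_ap_right, t)
  iqr <- stats::IQR(d)
  if (iqr < 1e-12) return(0L)
  prom <- min_prom_frac * iqr
  # level gate: a step extremum must reach toward the extreme separation;
  # a mid-level shoulder (feet level while standing) is not a step
  gate <- function(v) {
    med <- stats::median(v)
    thr <- med + 0.5 * (stats::quantile(v, 0.98, names = FALSE) - med)
    idx <- peaks_with_prominence(v, t, prom, min_sep_s)
    idx[v[idx] >= thr]
  }
  as.integer(length(gate(d)) + length(gate(-d)))
}

#' Grand summary rows of a cohort table
#'
#' Computes the grand `mean` and sample (n-1) `std` row of a per-row cohort
#' table: one row per subject-condition, one column per gait parameter.
#' Means are pairwise complete (missing cells skipped per column); `std`
#' is `NA` for columns with fewer than two observations.
#'
#' @param rows A data frame/tibble of per-subject-condition values;
#'   non-numeric columns are ignored.
#' @return A tibble with a `statistic` column (`"mean"`, `"std"`) and one
#'   column per numeric input column.
#' @examples
#' summarize_cohort(tibble::tibble(gait_speed_mps = c(0.876, 1.019, 0.389, 0.797)))
#' @export
summarize_cohort <- function(rows) {
  num <- rows[vapply(rows, is.numeric, logical(1))]
  if (!ncol(num)) stop("no numeric columns to summarize", call. = FALSE)
  mean_row <- vapply(num, function(v) mean(v, na.rm = TRUE), numeric(1))
  std_row <- vapply(num, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v)
  }, numeric(1))
  out <- tibble::as_tibble(rbind(mean_row, std_row))
  dplyr::bind_cols(tibble::tibble(statistic = c("mean", "std")), out)
}

#' Per-condition spatio-temporal summary from per-step data
#'
#' Two-level averaging: step lengths are averaged across steps within each
#' trial, then trial means are averaged across trials of the same
#' subject-condition. Step-length spread is the sample standard deviation
#' across all steps of the subject-condition; step counts are summed
#' across trials; gait speed is the mean of per-trial speeds.
#'
#' @param steps A tibble of per-step records with columns `subject_id`,
#'   `condition`, `trial`, `side` (`"left"`/`"right"`), `step_length_m`,
#'   and per-trial `gait_speed_mps` (repeated within a trial).
#' @return One row per subject-condition with columns mirroring a cohort
#'   gait table: step length mean/std per side, gait speed, step counts.
#' @export
summarize_trials <- function(steps) {
  if (!nrow(steps)) stop("no step data supplied", call. = FALSE)
  trial_level <- steps |>
    dplyr::group_by(.data$subject_id, .data$condition, .data$trial,
                    .data$side) |>
    dplyr::summarise(mean_len = mean(.data$step_length_m),
                     n = dplyr::n(),
                     speed = .data$gait_speed_mps[1], .groups = "drop")
  side_stats <- function(data, s) {
    tl <- trial_level[trial_level$side == s &
                        trial_level$subject_id == data$subject_id[1] &
                        trial_level$condition == data$condition[1], ]
    raw <- steps[steps$side == s &
                   steps$subject_id == data$subject_id[1] &
                   steps$condition == data$condition[1], ]
    list(mean = if (nrow(tl)) mean(tl$mean_len) else NA_real_,
         std = if (nrow(raw) > 1) stats::sd(raw$step_length_m) else NA_real_,
         n = nrow(raw))
  }
  groups <- dplyr::distinct(steps, .data$subject_id, .data$condition)
  purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    l <- side_stats(g, "left"); r <- side_stats(g, "right")
    sp <- trial_level[trial_level$subject_id == g$subject_id &
                        trial_level$condition == g$condition, ]
    tibble::tibble(
      subject_id = g$subject_id, condition = g$condition,
      step_length_left_m = l$mean, step_length_right_m = r$mean,
      step_length_left_sd_m = l$std, step_length_right_sd_m = r$std,
      gait_speed_mps = mean(unique(sp$speed)),
      n_steps_left = l$n, n_steps_right = r$n)
  })
}

#' Bundled clinical cohort gait tables
#'
#' Loads one of the per-subject-condition gait summary tables shipped with
#' the package: `"lab_training"` (four training trials: step lengths, gait
#' speed, included steps), `"lab_test"` (15 laboratory test rows with
#' per-side step counts) or `"imu"` (nine wearable-sensor validation rows).
#' These are the worked-example inputs for [summarize_cohort()].
#'
#' @param which One of `"lab_training"`, `"lab_test"`, `"imu"`.
#' @return A tibble.
#' @export
cohort_table <- function(which = c("lab_training", "lab_test", "imu")) {
  which <- match.arg(which)
  fn <- c(lab_training = "lab_training_cohort.csv",
          lab_test = "lab_test_cohort.csv",
          imu = "imu_cohort.csv")[[which]]
  path <- system.file("extdata", fn, package = "gaitpartition")
  if (!nzchar(path)) stop("bundled table not found: ", fn, call. = FALSE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
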