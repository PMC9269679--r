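#' Construct a gait recording
#'
#' A gait recording bundles the simultaneously captured channels of one
#' walking trial — accelerometer, per-foot vertical ground reaction force,
#' EMG, marker trajectories — as named [signal_trace()] objects at their
#' native rates (typically 100 Hz for markers/accelerometers, 500–1000 Hz
#' for EMG and force plates). Traces keep their native rates; cross-rate
#' comparisons are always made in seconds. Optional ground-truth events
#' (force-plate or manual) ride along for validation.
#'
#' @param traces Named list of `signal_trace` objects; names must be unique
#'   and match each trace's channel label.
#' @param side Which side(s) the recording covers: `"left"`, `"right"`,
#'   `"both"`.
#' @param condition Walking condition: `"barefoot"` or `"shoes_orthotics"`.
#' @param subject_id Subject identifier.
#' @param truth_events Optional `gait_events` tibble of ground-truth events.
#' @return An object of class `gait_recording`.
#' @export
gait_recording <- function(traces, side = c("both", "left", "right"),
                           condition = c("barefoot", "shoes_orthotics"),
                           subject_id = "anonymous", truth_events = NULL) {
  side <- match.arg(side)
  condition <- match.arg(condition)
  if (!is.list(traces) || is.null(names(traces)) ||
      any(!nzchar(names(traces)))) {
    stop("`traces` must be a named list of signal_trace objects", call. = FALSE)
  }
  if (anyDuplicated(names(traces))) {
    stop("duplicate channel name: ",
         names(traces)[duplicated(names(traces))][1L], call. = FALSE)
  }
  ok <- vapply(traces, inherits, logical(1), what = "signal_trace")
  if (!all(ok)) {
    stop("trace(s) not signal_trace objects: ",
         paste(names(traces)[!ok], collapse = ", "), call. = FALSE)
  }
  # all traces must cover overlapping time spans
  if (length(traces) > 1) {
    starts <- vapply(traces, trace_t0, numeric(1))
    ends <- vapply(traces, function(x) trace_t0(x) + trace_duration(x),
                   numeric(1))
    if (max(starts) >= min(ends)) {
      stop("traces do not share an overlapping time span", call. = FALSE)
    }
  }
  if (!is.null(truth_events)) validate_events(truth_events)
  structure(list(traces = traces, side = side, condition = condition,
                 subject_id = subject_id, truth_events = truth_events),
            class = "gait_recording")
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording> subject '%s', side %s, condition %s\n",
              x$subject_id, x$side, x$condition))
  for (nm in names(x$traces)) {
    tr <- x$traces[[nm]]
    cat(sprintf("  %-14s %6d samples @ %6g Hz  [%s]\n", nm, nrow(tr),
                trace_rate(tr), trace_units(tr)))
  }
  if (!is.null(x$truth_events)) {
    cat(sprintf("  truth: %d events\n", nrow(x$truth_events)))
  }
  invisible(x)
}

read_channel_csv <- function(path, column = "value") {
  if (!file.exists(path)) stop("channel file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"time_s" %in% names(df)) {
    stop("channel file lacks 'time_s' column: ", path, call. = FALSE)
  }
  if (!column %in% names(df)) {
    stop(sprintf("channel file %s lacks column '%s'", path, column),
         call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(df[[column]]))
  bad <- which(is.na(vals) | !is.finite(vals))
  if (length(bad)) {
    stop(sprintf("non-numeric or missing cell in %s, column '%s', row %d ('%s')",
                 path, column, bad[1L], df[[column]][bad[1L]]), call. = FALSE)
  }
  times <- suppressWarnings(as.numeric(df$time_s))
  badt <- which(is.na(times))
  if (length(badt)) {
    stop(sprintf("non-numeric cell in %s, column 'time_s', row %d",
                 path, badt[1L]), call. = FALSE)
  }
  list(time_s = times, value = vals)
}

#' Read a gait recording from a channel manifest
#'
#' The on-disk layout is one CSV per channel (columns `time_s,value`) or one
#' wide CSV (`time_s` plus one column per channel at a shared rate), tied
#' together by a YAML manifest:
#'
#' ```yaml
#' subject_id: s01
#' side: both
#' condition: barefoot
#' truth_events: truth.csv        # optional
#' channels:
#'   acc_foot_r: {file: acc.csv, rate_hz: 100, units: "m/s^2", role: accelerometer}
#'   grf_r:      {file: grf.csv,  rate_hz: 1000, units: "N",   role: grf}
#' ```
#'
#' A channel entry may add `column:` to pick a column of a wide CSV
#' (default: `value`, falling back to the channel name). Each channel's
#' declared `rate_hz` is checked against the file's time column; a mismatch
#' beyond half a sample period is an error — the reader never resamples.
#'
#' @param manifest Path to the YAML manifest; relative channel-file paths
#'   are resolved against its directory.
#' @return A [gait_recording()].
#' @export
read_recording <- function(manifest) {
  if (!file.exists(manifest)) {
    stop("manifest not found: ", manifest, call. = FALSE)
  }
  m <- yaml::read_yaml(manifest)
  if (is.null(m$channels) || !length(m$channels)) {
    stop("manifest declares no channels", call. = FALSE)
  }
  base <- dirname(manifest)
  traces <- list()
  for (nm in names(m$channels)) {
    spec <- m$channels[[nm]]
    if (is.null(spec$file) || is.null(spec$rate_hz)) {
      stop(sprintf("channel '%s' lacks file or rate_hz in manifest", nm),
           call. = FALSE)
    }
    path <- spec$file
    if (!grepl("^(/|[A-Za-z]:)", path)) path <- file.path(base, path)
    col <- spec$column %||% "value"
    raw <- tryCatch(read_channel_csv(path, col), error = function(e) {
      if (col == "value" && grepl("lacks column", conditionMessage(e))) {
        read_channel_csv(path, nm)   # wide CSV: column named as the channel
      } else stop(e)
    })
    rate <- as.numeric(spec$rate_hz)
    n <- length(raw$value)
    if (n >= 2) {
      span <- raw$time_s[n] - raw$time_s[1L]
      expected_span <- (n - 1L) / rate
      if (abs(span - expected_span) > 0.5 / rate) {
        stop(sprintf(
          "channel '%s': declared rate %g Hz inconsistent with time column (span %.4f s over %d samples)",
          nm, rate, span, n), call. = FALSE)
      }
    }
    traces[[nm]] <- signal_trace(raw$value, rate_hz = rate,
                                 t0_s = if (n) raw$time_s[1L] else 0,
                                 channel = nm, units = spec$units %||% "")
  }
  truth <- NULL
  if (!is.null(m$truth_events)) {
    tp <- m$truth_events
    if (!grepl("^(/|[A-Za-z]:)", tp)) tp <- file.path(base, tp)
    truth <- read_events(tp)
  }
  gait_recording(traces,
                 side = m$side %||% "both",
                 condition = m$condition %||% "barefoot",
                 subject_id = m$subject_id %||% "anonymous",
                 truth_events = truth)
}

#' Write a gait recording as manifest + channel CSVs
#'
#' Inverse of [read_recording()]: writes one `time_s,value` CSV per channel
#' (9 significant digits, so read-back matches within text precision), the
#' truth events if present, and a `manifest.yaml` naming them.
#'
#' @param rec A `gait_recording`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  channels <- list()
  for (nm in names(rec$traces)) {
    tr <- rec$traces[[nm]]
    fn <- paste0(nm, ".csv")
    df <- data.frame(time_s = formatC(tr$time_s, digits = 9, format = "g"),
                     value = formatC(tr$value, digits = 9, format = "g"))
    utils::write.csv(df, file.path(dir, fn), row.names = FALSE, quote = FALSE)
    channels[[nm]] <- list(file = fn, rate_hz = trace_rate(tr),
                           units = trace_units(tr))
  }
  m <- list(subject_id = rec$subject_id, side = rec$side,
            condition = rec$condition, channels = channels)
  if (!is.null(rec$truth_events)) {
    write_events(rec$truth_events, file.path(dir, "truth.csv"))
    m$truth_events <- "truth.csv"
  }
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(m, path)
  invisible(path)
}
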