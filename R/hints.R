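#' Construct swing-phase hints
#'
#' A hint is the few-shot training unit of the partitioner: a user-annotated
#' interval on one channel marking a single swing phase, running from
#' foot-off to the next foot-contact. Hints are held as a tidy tibble with
#' columns `channel`, `start_s`, `end_s` and `polarity`.
#'
#' `polarity` records how the annotated channel relates to the template:
#' `"as_is"` matches the signal directly, `"inverted"` matches its negation
#' (an accelerometer mounted the other way round, or a walking-direction
#' reversal in laboratory coordinates), and `"auto"` (the default) tries
#' both and keeps whichever matches better.
#'
#' @param channel Channel label the interval was drawn on.
#' @param start_s,end_s Swing interval bounds in seconds (`start_s < end_s`).
#' @param polarity `"auto"`, `"as_is"` or `"inverted"`.
#' @return A tibble of class `gait_hints`.
#' @examples
#' gait_hint("acc_foot_r", 1.20, 1.62)
#' @export
gait_hint <- function(channel, start_s, end_s, polarity = "auto") {
  h <- tibble::tibble(
    channel = as.character(channel),
    start_s = as.numeric(start_s),
    end_s = as.numeric(end_s),
    polarity = as.character(polarity)
  )
  as_gait_hints(h)
}

as_gait_hints <- function(df) {
  stopifnot(all(c("channel", "start_s", "end_s") %in% names(df)))
  if (is.null(df$polarity)) df$polarity <- "auto"
  df$polarity[is.na(df$polarity)] <- "auto"
  h <- tibble::as_tibble(df[c("channel", "start_s", "end_s", "polarity")])
  bad_pol <- setdiff(unique(h$polarity), c("auto", "as_is", "inverted"))
  if (length(bad_pol)) {
    stop("unknown hint polarity: ", paste(bad_pol, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(h$start_s < h$end_s))
  if (length(bad)) {
    stop(sprintf("hint %d has start_s >= end_s (%.4f >= %.4f)",
                 bad[1L], h$start_s[bad[1L]], h$end_s[bad[1L]]), call. = FALSE)
  }
  h <- dplyr::arrange(h, .data$start_s)
  structure(h, class = c("gait_hints", class(tibble::tibble())))
}

#' Read or write hints as JSON lines
#'
#' Hints are stored one JSON object per line:
#' `{"channel": "acc_foot_r", "start_s": 1.20, "end_s": 1.62, "polarity": "auto"}`
#' with `polarity` optional. `read_hints()` validates every record
#' (`start_s < end_s`, known polarity) and returns hints sorted by start
#' time; if `channels` is supplied, hints on unknown channels are an error.
#'
#' @param path JSON-lines file path.
#' @param channels Optional character vector of declared channel names.
#' @return A `gait_hints` tibble.
#' @export
read_hints <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("hint file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop(sprintf(
                      "malformed hint record on line %d: %s", i,
                      conditionMessage(e)), call. = FALSE))
    if (is.null(obj$channel) || is.null(obj$start_s) || is.null(obj$end_s)) {
      stop(sprintf("hint record on line %d lacks channel/start_s/end_s", i),
           call. = FALSE)
    }
    tibble::tibble(channel = as.character(obj$channel),
                   start_s = as.numeric(obj$start_s),
                   end_s = as.numeric(obj$end_s),
                   polarity = if (is.null(obj$polarity)) "auto"
                              else as.character(obj$polarity))
  })
  h <- as_gait_hints(dplyr::bind_rows(recs))
  if (!is.null(channels)) {
    unknown <- setdiff(unique(h$channel), channels)
    if (length(unknown)) {
      stop("hint channel(s) not in recording: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  h
}

#' @rdname read_hints
#' @param hints A `gait_hints` tibble.
#' @export
write_hints <- function(hints, path) {
  lines <- vapply(seq_len(nrow(hints)), function(i) {
    jsonlite::toJSON(list(channel = hints$channel[i],
                          start_s = hints$start_s[i],
                          end_s = hints$end_s[i],
                          polarity = hints$polarity[i]),
                     auto_unbox = TRUE, digits = 9)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Check hints against a recording: channel exists, interval inside the
# channel span, and duration longer than 2 samples.
validate_hints <- function(hints, rec) {
  for (i in seq_len(nrow(hints))) {
    ch <- hints$channel[i]
    if (!ch %in% names(rec$traces)) {
      stop(sprintf("hint channel '%s' not present in recording", ch),
           call. = FALSE)
    }
    tr <- rec$traces[[ch]]
    t0 <- trace_t0(tr)
    t1 <- t0 + trace_duration(tr)
    if (hints$start_s[i] < t0 - 1e-9 || hints$end_s[i] > t1 + 1e-9) {
      stop(sprintf("hint %d [%.3f, %.3f) outside channel '%s' span [%.3f, %.3f)",
                   i, hints$start_s[i], hints$end_s[i], ch, t0, t1),
           call. = FALSE)
    }
    if ((hints$end_s[i] - hints$start_s[i]) * trace_rate(tr) <= 2) {
      stop(sprintf("hint %d shorter than 3 samples on channel '%s'", i, ch),
           call. = FALSE)
    }
  }
  invisible(hints)
}
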