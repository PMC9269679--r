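#' Construct a set of gait events
#'
#' Gait events are the foot-contact (heel strike) and foot-off (toe off)
#' instants of one body side, held as a tidy tibble with columns
#' `event_type` (`"foot_contact"` or `"foot_off"`), `time_s` and `side`.
#' Validation enforces the gait alternation invariant: within a side, the
#' merged event sequence must alternate between contacts and offs (two
#' successive contacts with no off between them is physically impossible
#' for one foot).
#'
#' @param foot_contacts_s Ascending numeric vector of foot-contact times (s).
#' @param foot_offs_s Ascending numeric vector of foot-off times (s).
#' @param side `"left"` or `"right"`.
#' @param validate Check strict ascent and alternation (default `TRUE`).
#' @return A tibble of class `gait_events`, sorted by time.
#' @examples
#' gait_events(c(1.0, 2.1), 1.6, side = "right")
#' @export
gait_events <- function(foot_contacts_s = numeric(0),
                        foot_offs_s = numeric(0),
                        side = c("right", "left"),
                        validate = TRUE) {
  side <- match.arg(side)
  fc <- sort(as.numeric(foot_contacts_s))
  fo <- sort(as.numeric(foot_offs_s))
  ev <- tibble::tibble(
    event_type = c(rep("foot_contact", length(fc)), rep("foot_off", length(fo))),
    time_s = c(fc, fo),
    side = side
  )
  ev <- dplyr::arrange(ev, .data$time_s, .data$event_type)
  ev <- structure(ev, class = c("gait_events", class(tibble::tibble())))
  if (validate) validate_events(ev)
  ev
}

as_gait_events <- function(df, validate = TRUE) {
  stopifnot(all(c("event_type", "time_s", "side") %in% names(df)))
  ev <- tibble::as_tibble(df[c("event_type", "time_s", "side")])
  ev <- dplyr::arrange(ev, .data$time_s, .data$event_type)
  ev <- structure(ev, class = c("gait_events", class(tibble::tibble())))
  if (validate) validate_events(ev)
  ev
}

#' Validate a gait event table
#'
#' Checks that event types are known, times are finite and strictly
#' ascending within each type, and that contacts and offs alternate within
#' each side. Errors name the first offending pair.
#'
#' @param events A `gait_events` tibble (or coercible data frame).
#' @return The input, invisibly, if valid.
#' @export
validate_events <- function(events) {
  bad_type <- setdiff(unique(events$event_type), c("foot_contact", "foot_off"))
  if (length(bad_type)) {
    stop("unknown event_type: ", paste(bad_type, collapse = ", "), call. = FALSE)
  }
  if (anyNA(events$time_s) || !all(is.finite(events$time_s))) {
    stop("event times must be finite", call. = FALSE)
  }
  for (s in unique(events$side)) {
    ev <- events[events$side == s, ]
    ev <- ev[order(ev$time_s), ]
    for (ty in c("foot_contact", "foot_off")) {
      tt <- ev$time_s[ev$event_type == ty]
      if (length(tt) > 1 && any(diff(tt) <= 0)) {
        stop(sprintf("%s times not strictly ascending on side '%s'", ty, s),
             call. = FALSE)
      }
    }
    if (nrow(ev) > 1) {
      rep_idx <- which(ev$event_type[-1] == ev$event_type[-nrow(ev)])
      if (length(rep_idx)) {
        i <- rep_idx[1L]
        stop(sprintf(
          "events on side '%s' do not alternate: consecutive %s at %.3f s and %.3f s",
          s, ev$event_type[i], ev$time_s[i], ev$time_s[i + 1L]), call. = FALSE)
      }
    }
  }
  invisible(events)
}

event_times <- function(events, type, side = NULL) {
  keep <- events$event_type == type
  if (!is.null(side)) keep <- keep & events$side == side
  sort(events$time_s[keep])
}

#' Write gait events to CSV
#'
#' Deterministic, line-ordered CSV with columns `event_type`, `time_s`,
#' `side`; times are written with 9 significant digits so a write/read
#' round trip reproduces the input.
#'
#' @param events A `gait_events` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)[, c("event_type", "time_s", "side")]
  df <- df[order(df$time_s, df$event_type), ]
  df$time_s <- formatC(df$time_s, digits = 9, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gait events from CSV
#'
#' Counterpart of [write_events()]. `read_manual_events()` is the ingestion
#' path for manually annotated ground-truth events: identical parsing, but
#' the alternation check is always enforced so annotation slips (e.g. two
#' contacts with no intervening foot-off) are caught at the door.
#'
#' @param path CSV file with columns `event_type`, `time_s`, `side`.
#' @param validate Enforce alternation/ascent (default `TRUE`).
#' @return A `gait_events` tibble.
#' @export
read_events <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("events file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("event_type", "time_s", "side")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("events file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$time_s <- as.numeric(df$time_s)
  as_gait_events(df, validate = validate)
}

#' @rdname read_events
#' @export
read_manual_events <- function(path) read_events(path, validate = TRUE)
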