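# Hint-driven partitioning of a gait recording into swing cycles, event
# extraction, and scoring against ground truth.

#' Build an initial template from a hint
#'
#' Extracts the hinted swing interval from the conditioned (FFT-smoothed +
#' KZ-filtered) channel of a recording. Conditioning happens before
#' extraction so the template and the searched signal live on the same
#' scale.
#'
#' @param rec A [gait_recording()].
#' @param hint One-row [gait_hint()] tibble (or one row of a hints tibble).
#' @param fspec A [filter_spec()].
#' @return A template payload: conditioned values, rate, duration, polarity.
#' @export
build_template <- function(rec, hint, fspec = filter_spec()) {
  validate_hints(hint, rec)
  ct <- condition_trace(rec$traces[[hint$channel[1]]], fspec)
  vals <- trace_window(ct, hint$start_s[1], hint$end_s[1])
  if (length(vals) < 3) stop("hint shorter than 3 samples", call. = FALSE)
  new_template(vals, trace_rate(ct), polarity = hint$polarity[1])
}

no_match_error <- function(channel) {
  structure(class = c("gaitpartition_no_match", "error", "condition"),
            list(message = paste0(
              "no window matched the template on channel '", channel,
              "' below the acceptance threshold; a new hint is required"),
              call = NULL))
}

same_boundaries <- function(a, b, tol_s) {
  nrow(a) == nrow(b) &&
    (nrow(a) == 0 ||
       (max(abs(a$start_s - b$start_s)) < tol_s &&
          max(abs(a$end_s - b$end_s)) < tol_s))
}

# Iterate match -> select -> refine on one conditioned trace until the
# selected cycle boundaries move by less than one sample.
iterate_template <- function(template, ct, params, quant = NULL) {
  rate <- trace_rate(ct)
  if (is.null(quant)) quant <- quantize(ct, params$levels)
  prev <- NULL
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(params$max_iter)) {
    iterations <- it
    cands <- match_template(template, ct, params, quant = quant)
    if (!nrow(cands)) {
      if (it == 1L) stop(no_match_error(trace_channel(ct)))
      break
    }
    sel <- select_cycles(cands, params$refractory_s,
                         channel = trace_channel(ct),
                         template_length_s = template$length_s)
    if (!is.null(prev) && same_boundaries(prev, sel, 1 / rate)) {
      prev <- sel
      converged <- TRUE
      break
    }
    prev <- sel
    newt <- refine_template(template, sel, ct)
    if (isFALSE(attr(newt, "refined"))) break
    template <- newt
  }
  if (is.null(prev)) stop(no_match_error(trace_channel(ct)))
  list(cycles = prev, template = template, iterations = iterations,
       converged = converged,
       mean_distance = if (nrow(prev)) mean(prev$score) else Inf)
}

# Match one template against a conditioned trace, honouring polarity.
match_one_template <- function(template, ct, params) {
  run <- function(trace) iterate_template(template, trace, params)
  pol <- template$polarity %||% "as_is"
  if (pol == "as_is") return(run(ct))
  neg <- trace_with_values(ct, -ct$value)
  if (pol == "inverted") return(run(neg))
  # auto: try both signs of the target signal, keep the better match
  res_pos <- tryCatch(run(ct), gaitpartition_no_match = function(e) NULL)
  res_neg <- tryCatch(run(neg), gaitpartition_no_match = function(e) NULL)
  if (is.null(res_pos) && is.null(res_neg)) {
    stop(no_match_error(trace_channel(ct)))
  }
  if (is.null(res_neg)) return(res_pos)
  if (is.null(res_pos)) return(res_neg)
  if (res_pos$mean_distance <= res_neg$mean_distance) res_pos else res_neg
}

#' Partition a recording into swing cycles from hints
#'
#' The package's core operation. Each hint seeds a template extracted from
#' the conditioned accelerometer channel; the template is slid across the
#' whole channel at several length scales, windows under the fuzzy Hamming
#' acceptance threshold become cycle candidates, overlapping candidates are
#' thinned greedily, and the template is re-estimated from the matched
#' instances. The loop repeats until the selected boundaries move by less
#' than one sample (at most `params$max_iter` iterations). Cycle sets from
#' multiple hints are merged by the same non-overlap selection.
#'
#' With hint polarity `"auto"` both the signal and its negation are
#' matched and the variant with the lower mean distance wins, so a
#' walking-direction or mounting-sign flip costs nothing.
#'
#' @param rec A [gait_recording()].
#' @param hints A [gait_hint()] tibble; every hint must lie on a channel of
#'   `rec`.
#' @param params A [template_params()].
#' @param fspec A [filter_spec()].
#' @param templates Optional list of pre-built template payloads (e.g. from
#'   other recordings via [build_template()]); used instead of `hints` when
#'   supplied, with `channel` naming the channel to search.
#' @param channel Channel searched when `templates` is given.
#' @return A `cycle_set` tibble (`start_s`, `end_s`, `score`) of
#'   non-overlapping swing intervals sorted by start time.
#' @section Errors: if no window scores below the acceptance threshold on
#'   the first iteration, a condition of class `gaitpartition_no_match` is
#'   raised — the trigger for annotating a new hint.
#' @export
partition_with_hints <- function(rec, hints = NULL, params = template_params(),
                                 fspec = filter_spec(), templates = NULL,
                                 channel = NULL) {
  if (is.null(templates)) {
    if (is.null(hints) || !nrow(hints)) {
      stop("at least one hint (or pre-built template) is required",
           call. = FALSE)
    }
    validate_hints(hints, rec)
    channel <- channel %||% hints$channel[1]
    templates <- lapply(seq_len(nrow(hints)), function(i) {
      build_template(rec, hints[i, , drop = FALSE], fspec)
    })
    chans <- unique(hints$channel)
  } else {
    if (is.null(channel)) stop("`channel` required with pre-built templates",
                               call. = FALSE)
    chans <- channel
  }
  if (!channel %in% names(rec$traces)) {
    stop(sprintf("channel '%s' not present in recording", channel),
         call. = FALSE)
  }
  results <- list()
  n_templates <- 0L
  for (ch in chans) {
    ct <- condition_trace(rec$traces[[ch]], fspec)
    idx <- if (is.null(hints)) seq_along(templates)
           else which(hints$channel == ch)
    for (i in idx) {
      n_templates <- n_templates + 1L
      # a template that matches nothing contributes no candidates; only
      # when every template fails is the no-match condition raised
      res <- tryCatch(match_one_template(templates[[i]], ct, params),
                      gaitpartition_no_match = function(e) NULL)
      if (!is.null(res)) results[[length(results) + 1L]] <- res
    }
  }
  if (!length(results)) stop(no_match_error(channel))
  if (length(results) == 1L && n_templates == 1L) {
    return(results[[1L]]$cycles)
  }
  pooled <- dplyr::bind_rows(lapply(results, function(r) {
    tibble::tibble(start_s = r$cycles$start_s, end_s = r$cycles$end_s,
                   distance = r$cycles$score)
  }))
  pooled <- dplyr::arrange(pooled, .data$distance, .data$start_s)
  select_cycles(pooled, params$refractory_s, channel = channel,
                template_length_s = stats::median(
                  vapply(results, function(r) r$template$length_s, numeric(1))))
}

#' Convert swing cycles to gait events
#'
#' A swing phase runs foot-off to foot-contact, so each cycle interval
#' yields a foot-off at its start and a foot-contact at its end.
#'
#' @param cycles A `cycle_set` tibble.
#' @param side `"left"` or `"right"`.
#' @return A [gait_events()] tibble.
#' @export
cycles_to_events <- function(cycles, side = c("right", "left")) {
  side <- match.arg(side)
  gait_events(foot_contacts_s = cycles$end_s, foot_offs_s = cycles$start_s,
              side = side)
}

#' Score predicted events against ground truth
#'
#' Each predicted event is matched to the nearest ground-truth event of the
#' same type within a matching window (default 0.5 s, about half a gait
#' cycle); absolute time differences are pooled over both event types.
#' `escalate` is `TRUE` when any per-event error exceeds `threshold_s`
#' (default 0.060 s) — the signal that the recording should be moved into
#' the training set and a new hint annotated.
#'
#' @param pred,truth [gait_events()] tibbles on the same side.
#' @param threshold_s Escalation bound on the per-event absolute error (s).
#' @param match_window_s Maximum predicted-to-truth distance for a pair to
#'   count as matched (s).
#' @return An object of class `gait_error_report`: per-event errors, their
#'   mean / sample (n-1) std / max, matched and unmatched counts, and the
#'   `escalate` flag. [tidy()] returns the per-event table, [glance()] the
#'   one-row summary.
#' @export
partition_error <- function(pred, truth, threshold_s = 0.060,
                            match_window_s = 0.5) {
  if (is.null(truth) || !nrow(truth)) {
    stop("ground-truth events are empty", call. = FALSE)
  }
  sides_p <- unique(pred$side); sides_t <- unique(truth$side)
  if (length(sides_p) && length(sides_t) &&
      !any(sides_p %in% sides_t)) {
    stop("predicted and truth events are on different sides", call. = FALSE)
  }
  rows <- list()
  n_unmatched_pred <- 0L
  matched_truth <- character(0)
  for (ty in c("foot_contact", "foot_off")) {
    pt <- sort(pred$time_s[pred$event_type == ty])
    tt <- sort(truth$time_s[truth$event_type == ty])
    for (p in pt) {
      if (!length(tt)) { n_unmatched_pred <- n_unmatched_pred + 1L; next }
      j <- which.min(abs(tt - p))
      if (abs(tt[j] - p) <= match_window_s) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          event_type = ty, pred_time_s = p, truth_time_s = tt[j],
          abs_err_s = abs(tt[j] - p))
        matched_truth <- c(matched_truth, paste(ty, j))
      } else {
        n_unmatched_pred <- n_unmatched_pred + 1L
      }
    }
  }
  per_event <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(event_type = character(0), pred_time_s = numeric(0),
                   truth_time_s = numeric(0), abs_err_s = numeric(0))
  errs <- per_event$abs_err_s
  out <- list(
    per_event = per_event,
    mean_s = if (length(errs)) mean(errs) else NA_real_,
    std_s = if (length(errs) > 1) stats::sd(errs) else NA_real_,
    max_s = if (length(errs)) max(errs) else NA_real_,
    n_matched = length(errs),
    n_unmatched_pred = n_unmatched_pred,
    n_unmatched_truth = nrow(truth) - length(unique(matched_truth)),
    threshold_s = threshold_s,
    escalate = length(errs) > 0 && any(errs > threshold_s)
  )
  class(out) <- "gait_error_report"
  out
}

#' @export
print.gait_error_report <- function(x, ...) {
  cat(sprintf(
    "<gait_error_report> %d matched events: mean %.4f s, std %s s, max %.4f s%s\n",
    x$n_matched, x$mean_s,
    if (is.na(x$std_s)) "NA" else sprintf("%.4f", x$std_s), x$max_s,
    if (x$escalate) sprintf("  [ESCALATE > %.3f s]", x$threshold_s) else ""))
  if (x$n_unmatched_pred || x$n_unmatched_truth) {
    cat(sprintf("  unmatched: %d predicted, %d truth\n",
                x$n_unmatched_pred, x$n_unmatched_truth))
  }
  invisible(x)
}

#' Tidy methods for fitted gait objects
#'
#' Broom-style accessors: `tidy()` returns the per-observation table of an
#' object (per-event errors of a `gait_error_report`, the per-sample state
#' path of a `gait_segmentation`), `glance()` a one-row model summary.
#'
#' @param x A `gait_error_report` or `gait_segmentation`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy gait_error_report
#' @export
tidy.gait_error_report <- function(x, ...) x$per_event

#' @rdname tidy.gait_error_report
#' @method glance gait_error_report
#' @export
glance.gait_error_report <- function(x, ...) {
  tibble::tibble(mean_s = x$mean_s, std_s = x$std_s, max_s = x$max_s,
                 n_matched = x$n_matched,
                 n_unmatched_pred = x$n_unmatched_pred,
                 n_unmatched_truth = x$n_unmatched_truth,
                 threshold_s = x$threshold_s, escalate = x$escalate)
}
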