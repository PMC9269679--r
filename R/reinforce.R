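# Reinforcement loop: partition every dataset with the current hint set,
# absorb escalating datasets into the training set with a fresh hint, and
# repeat until the remaining datasets all partition acceptably.

# First truth swing interval (foot-off -> next foot-contact) of a
# recording, on the requested side.
first_truth_swing <- function(rec, side) {
  tr <- rec$truth_events
  fo <- event_times(tr, "foot_off", side)
  fc <- event_times(tr, "foot_contact", side)
  for (o in fo) {
    nxt <- fc[fc > o]
    if (length(nxt)) return(c(o, nxt[1]))
  }
  stop(sprintf("recording '%s' has no complete truth swing on side %s",
               rec$subject_id, side), call. = FALSE)
}

#' Hint-to-step bookkeeping
#'
#' The training burden of the few-shot workflow: the number of annotated
#' hints as a percentage of the total number of steps partitioned.
#'
#' @param n_hints Number of hints in the training library.
#' @param n_steps Total steps across all datasets.
#' @return Percentage (0-100).
#' @examples
#' hint_fraction_pct(6, 567)   # ~1.06% of the steps
#' @export
hint_fraction_pct <- function(n_hints, n_steps) {
  if (n_steps <= 0) stop("`n_steps` must be positive", call. = FALSE)
  100 * n_hints / n_steps
}

#' Run the hint reinforcement loop over a set of recordings
#'
#' Starting from one (or more) annotated hints, every dataset is
#' partitioned with templates built from the current hint library and
#' scored against its ground-truth events. Any dataset whose per-event
#' error exceeds `threshold_s` — or where no window matches at all — is
#' transitioned into the training set: its first ground-truth swing
#' interval becomes a new hint, standing in for the human annotator. The
#' loop repeats over the remaining test datasets until none escalates or
#' every dataset has been absorbed into training.
#'
#' @param datasets Named list of [gait_recording()] objects, each carrying
#'   `truth_events`.
#' @param initial_hints A [gait_hint()] tibble annotated on
#'   `datasets[[hint_source]]`.
#' @param hint_source Name or index of the dataset the initial hints were
#'   drawn on (default the first).
#' @param channel Accelerometer channel matched on; default the channel of
#'   the first hint.
#' @param side Side scored against truth (default `"right"`).
#' @param threshold_s Escalation bound on per-event error (s), default
#'   0.060.
#' @param params A [template_params()].
#' @param fspec A [filter_spec()].
#' @return A list of class `gait_reinforcement`: `hints` (tibble with a
#'   `dataset` column), `membership` (dataset, status, rounds), `reports`
#'   (per-dataset `gait_error_report` or NULL for training sets),
#'   `n_hints`, `n_steps`, `hint_fraction_pct`, `rounds`.
#' @export
reinforcement_loop <- function(datasets, initial_hints, hint_source = 1L,
                               channel = NULL, side = "right",
                               threshold_s = 0.060,
                               params = template_params(),
                               fspec = filter_spec()) {
  if (is.null(names(datasets))) {
    names(datasets) <- sprintf("dataset_%02d", seq_along(datasets))
  }
  for (nm in names(datasets)) {
    if (is.null(datasets[[nm]]$truth_events)) {
      stop("dataset '", nm, "' lacks truth events", call. = FALSE)
    }
  }
  channel <- channel %||% initial_hints$channel[1]
  src <- if (is.character(hint_source)) hint_source else
    names(datasets)[hint_source]
  hints <- dplyr::mutate(initial_hints, dataset = src)
  templates <- lapply(seq_len(nrow(initial_hints)), function(i) {
    build_template(datasets[[src]], initial_hints[i, , drop = FALSE], fspec)
  })
  status <- stats::setNames(rep("test", length(datasets)), names(datasets))
  absorbed_round <- stats::setNames(rep(NA_integer_, length(datasets)),
                                    names(datasets))
  reports <- stats::setNames(vector("list", length(datasets)),
                             names(datasets))
  round <- 0L
  repeat {
    round <- round + 1L
    escalated <- character(0)
    for (nm in names(datasets)[status == "test"]) {
      rec <- datasets[[nm]]
      res <- tryCatch({
        cyc <- partition_with_hints(rec, params = params, fspec = fspec,
                                    templates = templates, channel = channel)
        ev <- cycles_to_events(cyc, side)
        partition_error(ev, rec$truth_events[rec$truth_events$side == side, ],
                        threshold_s = threshold_s)
      }, gaitpartition_no_match = function(e) NULL)
      reports[[nm]] <- res
      if (is.null(res) || res$escalate || res$n_matched == 0) {
        escalated <- c(escalated, nm)
      }
    }
    if (!length(escalated)) break
    for (nm in escalated) {
      status[nm] <- "training"
      absorbed_round[nm] <- round
      sw <- first_truth_swing(datasets[[nm]], side)
      h <- gait_hint(channel, sw[1], sw[2])
      hints <- dplyr::bind_rows(hints, dplyr::mutate(h, dataset = nm))
      templates <- c(templates,
                     list(build_template(datasets[[nm]], h, fspec)))
    }
    if (all(status == "training")) break
  }
  n_steps <- sum(vapply(datasets, function(r) {
    sum(r$truth_events$event_type == "foot_contact")
  }, numeric(1)))
  out <- list(
    hints = hints,
    membership = tibble::tibble(dataset = names(datasets),
                                status = unname(status),
                                absorbed_round = unname(absorbed_round)),
    reports = reports,
    n_hints = nrow(hints),
    n_steps = n_steps,
    hint_fraction_pct = hint_fraction_pct(nrow(hints), n_steps),
    rounds = round,
    threshold_s = threshold_s
  )
  class(out) <- "gait_reinforcement"
  out
}

#' @export
print.gait_reinforcement <- function(x, ...) {
  cat(sprintf(
    "<gait_reinforcement> %d hints over %d steps (%.2f%%), %d/%d datasets in training, %d round(s)\n",
    x$n_hints, x$n_steps, x$hint_fraction_pct,
    sum(x$membership$status == "training"), nrow(x$membership), x$rounds))
  invisible(x)
}

#' @rdname tidy.gait_error_report
#' @method tidy gait_reinforcement
#' @export
tidy.gait_reinforcement <- function(x, ...) {
  per <- lapply(x$membership$dataset, function(nm) {
    rep <- x$reports[[nm]]
    if (is.null(rep)) {
      tibble::tibble(dataset = nm, mean_s = NA_real_, max_s = NA_real_,
                     n_matched = 0L, escalate = TRUE)
    } else {
      tibble::tibble(dataset = nm, mean_s = rep$mean_s, max_s = rep$max_s,
                     n_matched = rep$n_matched, escalate = rep$escalate)
    }
  })
  dplyr::left_join(x$membership, dplyr::bind_rows(per), by = "dataset")
}

#' @rdname tidy.gait_error_report
#' @method glance gait_reinforcement
#' @export
glance.gait_reinforcement <- function(x, ...) {
  test <- x$membership$dataset[x$membership$status == "test"]
  errs <- unlist(lapply(test, function(nm) x$reports[[nm]]$per_event$abs_err_s))
  tibble::tibble(n_hints = x$n_hints, n_steps = x$n_steps,
                 hint_fraction_pct = x$hint_fraction_pct,
                 n_training = sum(x$membership$status == "training"),
                 n_test = length(test), rounds = x$rounds,
                 test_mean_err_s = if (length(errs)) mean(errs) else NA_real_,
                 test_max_err_s = if (length(errs)) max(errs) else NA_real_)
}
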