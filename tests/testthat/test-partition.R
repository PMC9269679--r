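test_that("a hint on a noiseless periodic signal recovers every cycle", {
  # motif followed by a quiet gap, repeated n times
  motif <- c(sin(seq(0, pi, length.out = 30)) * 4, rep(0, 70))
  n_rep <- 6
  x <- c(rep(0, 50), rep(motif, n_rep), rep(0, 50))
  rec <- gait_recording(list(acc = signal_trace(x, 100, channel = "acc")))
  hint <- gait_hint("acc", 0.50, 0.80, polarity = "as_is")
  cyc <- partition_with_hints(rec, hint, fspec = filter_spec(
    fft_cutoff_hz = NULL, kz_m = NULL))
  expect_equal(nrow(cyc), n_rep)
  expect_equal(sort(cyc$start_s), 0.5 + (0:(n_rep - 1)), tolerance = 0.011)
})

test_that("one hint partitions a synthetic recording within the error bound", {
  rec <- default_recording()
  hint <- first_swing_hint(rec)
  cyc <- partition_with_hints(rec, hint)
  expect_gte(nrow(cyc), 18)
  truth <- rec$truth_events[rec$truth_events$side == "right", ]
  rep <- partition_error(cycles_to_events(cyc, "right"), truth)
  expect_false(rep$escalate)
  expect_lte(rep$max_s, 0.060)
  # parameter recovery: swing-duration bias under 20 ms
  tr_off <- sort(truth$time_s[truth$event_type == "foot_off"])
  tr_con <- sort(truth$time_s[truth$event_type == "foot_contact"])
  true_sw <- tr_con - tr_off
  match_idx <- vapply(cyc$start_s, function(s) which.min(abs(tr_off - s)),
                      integer(1))
  bias <- mean((cyc$end_s - cyc$start_s) - true_sw[match_idx])
  expect_lt(abs(bias), 0.02)
})

test_that("polarity 'auto' makes partitioning invariant to a global sign flip", {
  rec <- default_recording()
  hint <- first_swing_hint(rec)
  cyc <- partition_with_hints(rec, hint)
  neg <- rec
  neg$traces$acc_foot_r <- signal_trace(-rec$traces$acc_foot_r$value, 100,
                                        channel = "acc_foot_r",
                                        units = "m/s^2")
  cyc_neg <- partition_with_hints(neg, hint)
  expect_equal(cyc_neg$start_s, cyc$start_s, tolerance = 1e-9)
  expect_equal(cyc_neg$end_s, cyc$end_s, tolerance = 1e-9)
})

test_that("partitioning is equivariant under time translation", {
  motif <- c(sin(seq(0, pi, length.out = 30)) * 4, rep(0, 70))
  x <- c(rep(0, 50), rep(motif, 4), rep(0, 50))
  fs <- filter_spec(fft_cutoff_hz = NULL, kz_m = NULL)
  rec <- gait_recording(list(acc = signal_trace(x, 100, channel = "acc")))
  cyc <- partition_with_hints(rec, gait_hint("acc", 0.50, 0.80, "as_is"),
                              fspec = fs)
  shift <- 37  # samples
  rec2 <- gait_recording(list(acc = signal_trace(c(rep(0, shift), x), 100,
                                                 channel = "acc")))
  cyc2 <- partition_with_hints(rec2,
                               gait_hint("acc", 0.50 + shift / 100,
                                         0.80 + shift / 100, "as_is"),
                               fspec = fs)
  expect_equal(cyc2$start_s, cyc$start_s + shift / 100, tolerance = 1e-9)
  expect_equal(cyc2$end_s, cyc$end_s + shift / 100, tolerance = 1e-9)
})

test_that("cycles convert to alternating events and back out of a recording", {
  cyc <- select_cycles(tibble::tibble(start_s = c(1.0, 2.2),
                                      end_s = c(1.42, 2.6),
                                      distance = c(0, 0)), 0.1)
  ev <- cycles_to_events(cyc, "right")
  expect_equal(ev$time_s[ev$event_type == "foot_off"], c(1.0, 2.2))
  expect_equal(ev$time_s[ev$event_type == "foot_contact"], c(1.42, 2.6))
  expect_silent(validate_events(ev))
  empty <- cycles_to_events(cyc[0, ], "left")
  expect_equal(nrow(empty), 0)

  # swing intervals interleave with the generator's stance phases
  rec <- default_recording()
  cyc <- partition_with_hints(rec, first_swing_hint(rec))
  ev <- cycles_to_events(cyc, "right")
  truth <- rec$truth_events[rec$truth_events$side == "right", ]
  tr_con <- sort(truth$time_s[truth$event_type == "foot_contact"])
  tr_off <- sort(truth$time_s[truth$event_type == "foot_off"])
  for (i in seq_len(nrow(cyc))) {
    # each detected swing contains no true contact strictly inside it
    inside <- tr_con > cyc$start_s[i] + 0.06 & tr_con < cyc$end_s[i] - 0.06
    expect_false(any(inside))
  }
})

test_that("partition error reports match, spread and the escalation flag", {
  truth <- gait_events(c(1.0, 2.0, 3.0), c(1.4, 2.4, 3.4), side = "right")
  expect_identical(partition_error(truth, truth)$mean_s, 0)
  expect_identical(partition_error(truth, truth)$max_s, 0)
  expect_false(partition_error(truth, truth)$escalate)

  shifted <- gait_events(c(1.07, 2.0, 3.0), c(1.4, 2.4, 3.4), side = "right")
  rep <- partition_error(shifted, truth, threshold_s = 0.060)
  expect_true(rep$escalate)
  expect_equal(rep$max_s, 0.07)

  # uniformly jittered events: pooled mean equals the oracle mean |jitter|
  set.seed(77)
  fc <- seq(1, 12, by = 1.1)
  fo <- fc + 0.45
  truth2 <- gait_events(fc, fo, side = "left")
  jit <- runif(length(fc) * 2, -0.03, 0.03)
  pred <- gait_events(fc + jit[seq_along(fc)],
                      fo + jit[length(fc) + seq_along(fo)], side = "left")
  rep2 <- partition_error(pred, truth2)
  expect_equal(rep2$mean_s, mean(abs(jit)), tolerance = 1e-12)
  expect_equal(rep2$n_matched, length(jit))

  expect_error(partition_error(truth, truth[0, ]), "empty")
  expect_error(partition_error(truth,
                               gait_events(1, 1.4, side = "left")),
               "different sides")
  g <- glance(rep2)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$n_matched, length(jit))
  expect_equal(nrow(tidy(rep2)), length(jit))
})
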