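test_that("an empty spec yields quiet channels and no events", {
  rec <- generate_recording(synthetic_gait_spec(n_steps = 0, seed = 1))
  expect_equal(nrow(rec$truth_events), 0)
  expect_true(all(rec$traces$grf_r$value == 0))
  expect_lt(max(abs(rec$traces$emg_gas_r$value)), 0.1)
})

test_that("commanded stance durations are exact without jitter", {
  spec <- synthetic_gait_spec(n_steps = 6, cadence_hz = 1.0,
                              stance_fraction = 0.6, step_time_cv = 0,
                              seed = 2)
  rec <- generate_recording(spec)
  for (s in c("left", "right")) {
    tr <- rec$truth_events[rec$truth_events$side == s, ]
    fc <- sort(tr$time_s[tr$event_type == "foot_contact"])
    fo <- sort(tr$time_s[tr$event_type == "foot_off"])
    # stance runs contact -> next off
    stance <- vapply(fc, function(c) {
      nxt <- fo[fo > c]
      if (length(nxt)) nxt[1] - c else NA_real_
    }, numeric(1))
    stance <- stance[!is.na(stance)]
    expect_gt(length(stance), 0)
    expect_equal(stance, rep(0.6, length(stance)), tolerance = 1e-9)
  }
})

test_that("generated force plates agree with the commanded events", {
  rec <- generate_recording(synthetic_gait_spec(n_steps = 12, seed = 9))
  for (s in c("left", "right")) {
    ch <- if (s == "left") "grf_l" else "grf_r"
    ev <- detect_events_forceplate(rec$traces[[ch]], side = s)
    truth <- rec$truth_events[rec$truth_events$side == s, ]
    expect_equal(nrow(ev), nrow(truth))
    rep <- partition_error(ev, truth, threshold_s = 1e-3)
    expect_lte(rep$max_s, 1e-3)    # within one 1000 Hz sample
    expect_equal(rep$n_unmatched_truth, 0)
  }
})

test_that("recordings are bit-reproducible from their seed", {
  a <- generate_recording(synthetic_gait_spec(n_steps = 5, seed = 31))
  b <- generate_recording(synthetic_gait_spec(n_steps = 5, seed = 31))
  for (nm in names(a$traces)) {
    expect_identical(a$traces[[nm]]$value, b$traces[[nm]]$value)
  }
  expect_identical(a$truth_events$time_s, b$truth_events$time_s)
  c1 <- generate_cohort(3, n_steps = 6, seed = 4)
  c2 <- generate_cohort(3, n_steps = 6, seed = 4)
  expect_identical(c1$subject_03$traces$acc_foot_r$value,
                   c2$subject_03$traces$acc_foot_r$value)
})

test_that("a degenerate cohort reduces to a single-spec recording", {
  rng <- list(cadence_hz = c(1, 1), stance_fraction = c(0.6, 0.6),
              step_length_m = c(0.45, 0.45), noise_sd = c(0.5, 0.5),
              step_time_cv = c(0.03, 0.03))
  co <- generate_cohort(1, ranges = rng, n_steps = 8, seed = 2)
  direct <- generate_recording(synthetic_gait_spec(
    n_steps = 8, cadence_hz = 1, stance_fraction = 0.6, step_length_m = 0.45,
    noise_sd = 0.5, step_time_cv = 0.03, seed = 2001))
  expect_identical(co[[1]]$traces$acc_foot_r$value,
                   direct$traces$acc_foot_r$value)
  expect_identical(co[[1]]$truth_events$time_s, direct$truth_events$time_s)
})

test_that("cohort draws stay inside their ranges and speeds are recovered", {
  co <- generate_cohort(6, ranges = list(step_length_m = c(0.25, 0.55),
                                         cadence_hz = c(0.7, 1.2)),
                        n_steps = 8, seed = 11)
  specs <- attr(co, "specs")
  for (i in seq_along(co)) {
    sp <- specs[[i]]
    expect_gte(sp$cadence_hz, 0.7); expect_lte(sp$cadence_hz, 1.2)
    v <- gait_speed(marker_xyz(co[[i]], "asis"))
    expect_lt(abs(v - sp$walking_speed_mps), 0.03)
    # implied speed range for these draws: 2 * 0.25 * 0.7 .. 2 * 0.55 * 1.2
    expect_gte(v, 2 * 0.25 * 0.7 - 0.03)
    expect_lte(v, 2 * 0.55 * 1.2 + 0.03)
  }
  expect_error(generate_cohort(2, ranges = list(bogus = c(0, 1))), "unknown")
})

test_that("infeasible specs are rejected", {
  expect_error(synthetic_gait_spec(stance_fraction = 1.2), "stance_fraction")
  expect_error(synthetic_gait_spec(step_time_cv = 0.4), "exceed the cycle")
  expect_error(synthetic_gait_spec(n_steps = -1), "n_steps")
})
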