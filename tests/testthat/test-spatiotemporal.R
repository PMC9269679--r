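test_that("step lengths are the inter-malleolus distance at contact", {
  t <- (0:499) / 100
  left <- tibble::tibble(time_s = t, x = 0, y = 0, z = 0)
  right <- tibble::tibble(time_s = t, x = 0.5, y = 0, z = 0)
  ev <- gait_events(2.0, numeric(0), side = "right")
  sl <- step_lengths(left, right, ev)
  expect_equal(nrow(sl), 1)
  expect_equal(sl$step_length_m, 0.5)
  expect_equal(sl$side, "right")

  expect_equal(nrow(step_lengths(left, right, gait_events(side = "right"))), 0)
  expect_error(step_lengths(left, right,
                            gait_events(99, numeric(0), side = "right")),
               "outside")
})

test_that("generator recordings return the commanded spatio-temporal values", {
  spec <- synthetic_gait_spec(n_steps = 10, cadence_hz = 1.0,
                              step_length_m = 0.45, seed = 6)
  rec <- generate_recording(spec)
  sl <- step_lengths(marker_xyz(rec, "ank_l"), marker_xyz(rec, "ank_r"),
                     rec$truth_events)
  expect_equal(nrow(sl), 20)
  expect_true(all(abs(sl$step_length_m - 0.45) < 0.02))

  sp <- gait_speed(marker_xyz(rec, "asis"))
  expect_lt(abs(sp - spec$walking_speed_mps), 0.03)

  n <- count_steps(rec$traces$ank_l_x, rec$traces$ank_r_x)
  expect_identical(n, 20L)
})

test_that("gait speed is net displacement over time", {
  t <- (0:499) / 100
  asis <- tibble::tibble(time_s = t, x = 1.0 * t, y = 0, z = 0.9)
  expect_equal(gait_speed(asis), 1.0, tolerance = 1e-12)
  still <- tibble::tibble(time_s = t, x = 2, y = 1, z = 0.9)
  expect_equal(gait_speed(still), 0)
  expect_error(gait_speed(asis[1, ]), "zero duration")
})

test_that("step counting counts prominent extrema of the ankle-distance signal", {
  t <- (0:999) / 100
  mono <- signal_trace(t, 100)
  flat <- signal_trace(rep(0, 1000), 100)
  expect_identical(count_steps(mono, flat), 0L)
  # 8 full periods: 8 maxima + 8 minima = 16 steps
  d <- signal_trace(sin(2 * pi * 0.8 * t), 100)
  expect_identical(count_steps(d, flat), 16L)
})

test_that("cohort grand rows use pairwise-complete means and n-1 std", {
  speeds <- tibble::tibble(gait_speed_mps = c(0.876, 1.019, 0.389, 0.797))
  g <- summarize_cohort(speeds)
  expect_equal(round(g$gait_speed_mps[g$statistic == "mean"], 3), 0.770)
  expect_equal(round(g$gait_speed_mps[g$statistic == "std"], 3), 0.270)

  # the printed spread is reproduced only under the sample (n-1) convention
  lens <- c(0.37, 0.465, 0.282, 0.457)
  sd_n1 <- sd(lens)
  sd_n <- sqrt(mean((lens - mean(lens))^2))
  expect_equal(round(sd_n1, 3), 0.086)
  expect_false(round(sd_n, 3) == 0.086)
  g2 <- summarize_cohort(tibble::tibble(step_length_left_m = lens))
  expect_equal(g2$step_length_left_m[g2$statistic == "std"], sd_n1)

  # missing cells are skipped pairwise; single observation has no std
  g3 <- summarize_cohort(tibble::tibble(a = c(1, NA, 3), b = c(2, NA, NA)))
  expect_equal(g3$a[g3$statistic == "mean"], 2)
  expect_equal(g3$b[g3$statistic == "mean"], 2)
  expect_true(is.na(g3$b[g3$statistic == "std"]))
})

test_that("per-step data summarize through trial then condition levels", {
  steps <- tibble::tibble(
    subject_id = "s1", condition = "barefoot",
    trial = rep(c("t1", "t2"), each = 4),
    side = rep(c("left", "right"), 4),
    step_length_m = c(0.40, 0.50, 0.42, 0.52, 0.44, 0.54, 0.46, 0.56),
    gait_speed_mps = rep(c(1.0, 1.2), each = 4))
  s <- summarize_trials(steps)
  expect_equal(nrow(s), 1)
  expect_equal(s$step_length_left_m, mean(c(mean(c(0.40, 0.42)),
                                            mean(c(0.44, 0.46)))))
  expect_equal(s$gait_speed_mps, 1.1)
  expect_equal(s$n_steps_left, 4L)
  expect_equal(s$n_steps_right, 4L)
})
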