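test_that("signal traces enforce their invariants", {
  tr <- signal_trace(1:500 / 100, rate_hz = 100)
  expect_equal(nrow(tr), 500)
  expect_equal(trace_duration(tr), 5)
  # time of sample i is t0 + i/rate
  expect_equal(tr$time_s[1], 0)
  expect_equal(tr$time_s[101], 1)
  tr2 <- signal_trace(1:10, rate_hz = 10, t0_s = 2.5)
  expect_equal(tr2$time_s[1], 2.5)

  expect_error(signal_trace(c(1, NaN, 3), 100), "non-finite")
  expect_error(signal_trace(c(1, NA, 3), 100), "non-finite")
  expect_error(signal_trace(1:3, rate_hz = 0), "rate_hz")
  expect_error(signal_trace(1:3, rate_hz = -5), "rate_hz")
})

test_that("recordings validate channel names and spans", {
  a <- signal_trace(rnorm(100), 100, channel = "a")
  b <- signal_trace(rnorm(1000), 1000, channel = "b")
  rec <- gait_recording(list(a = a, b = b))
  expect_s3_class(rec, "gait_recording")
  expect_error(gait_recording(list(a, b)), "named list")
  far <- signal_trace(rnorm(100), 100, t0_s = 50, channel = "far")
  expect_error(gait_recording(list(a = a, far = far)), "overlapping")
})

test_that("recording write/read round trip preserves traces", {
  rec <- generate_recording(synthetic_gait_spec(n_steps = 3, seed = 7))
  dir <- withr::local_tempdir()
  read_back <- read_recording(write_recording(rec, dir))
  expect_setequal(names(read_back$traces), names(rec$traces))
  for (nm in names(rec$traces)) {
    expect_equal(read_back$traces[[nm]]$value, rec$traces[[nm]]$value,
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(trace_rate(read_back$traces[[nm]]),
                 trace_rate(rec$traces[[nm]]))
  }
  expect_equal(as.data.frame(read_back$truth_events),
               as.data.frame(rec$truth_events), tolerance = 1e-8)
})

test_that("ingestion rejects non-numeric cells, naming the location", {
  dir <- withr::local_tempdir()
  writeLines(c("time_s,value", "0,1.0", "0.01,NaN", "0.02,3.0"),
             file.path(dir, "bad.csv"))
  writeLines(c("channels:", "  acc:", "    file: bad.csv", "    rate_hz: 100"),
             file.path(dir, "manifest.yaml"))
  err <- expect_error(read_recording(file.path(dir, "manifest.yaml")))
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "value")
})

test_that("ingestion rejects a declared rate inconsistent with the time column", {
  dir <- withr::local_tempdir()
  df <- data.frame(time_s = (0:99) / 100, value = rnorm(100))
  write.csv(df, file.path(dir, "acc.csv"), row.names = FALSE)
  writeLines(c("channels:", "  acc:", "    file: acc.csv", "    rate_hz: 250"),
             file.path(dir, "manifest.yaml"))
  expect_error(read_recording(file.path(dir, "manifest.yaml")),
               "inconsistent")
})

test_that("hints parse from JSON lines with validation", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"channel":"acc_foot_r","start_s":1.20,"end_s":1.62}', f)
  h <- read_hints(f)
  expect_equal(nrow(h), 1)
  expect_equal(h$end_s - h$start_s, 0.42)
  expect_equal(h$polarity, "auto")

  writeLines('{"channel":"acc_foot_r","start_s":2.0,"end_s":1.5}', f)
  expect_error(read_hints(f), "start_s >= end_s")

  # six records survive with order by start time
  starts <- c(5.1, 1.2, 3.3, 2.0, 6.6, 4.4)
  writeLines(sprintf(
    '{"channel":"acc_foot_r","start_s":%g,"end_s":%g}', starts, starts + 0.4),
    f)
  h6 <- read_hints(f)
  expect_equal(nrow(h6), 6)
  expect_equal(h6$start_s, sort(starts))
  expect_error(read_hints(f, channels = c("emg_gas_r")), "not in recording")
})

test_that("events round trip through CSV and reject invariant violations", {
  ev <- gait_events(c(1.0, 2.1), 1.6, side = "right")
  f <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, f)
  expect_equal(length(readLines(f)), 4)   # header + three typed rows
  expect_equal(as.data.frame(read_events(f)), as.data.frame(ev),
               tolerance = 1e-9)

  write_events(gait_events(side = "right"), f)
  expect_equal(length(readLines(f)), 1)   # header only

  # random valid events round trip exactly within text precision
  set.seed(42)
  for (i in 1:5) {
    n <- sample(3:8, 1)
    fc <- cumsum(runif(n, 0.8, 1.4))
    fo <- fc + runif(n, 0.3, 0.5)
    ev <- gait_events(fc, fo, side = sample(c("left", "right"), 1))
    write_events(ev, f)
    expect_equal(read_events(f)$time_s, ev$time_s, tolerance = 1e-8)
  }
})

test_that("event validation rejects constructed violations", {
  # two contacts with no off between
  expect_error(gait_events(c(1.0, 1.2), numeric(0), side = "left"),
               "do not alternate")
  # non-ascending within a type (duplicates collapse to non-strict)
  expect_error(gait_events(c(1.0, 1.0), 1.5, side = "right"),
               "not strictly ascending|do not alternate")
  expect_error(
    as_gait_events(data.frame(event_type = "step", time_s = 1, side = "left")),
    "unknown event_type")
  ok <- gait_events(c(1.0, 2.1), 1.6, side = "right")
  expect_silent(validate_events(ok))
})
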