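test_that("quantization spans the percentile range and clips outliers", {
  q <- quantize(rep(5, 100), levels = 8)
  expect_equal(length(unique(q$codes)), 1)

  # ramp over [0, 1]: codes reproduce explicit edge comparisons
  v <- seq(0, 1, length.out = 101)
  q4 <- quantize(v, levels = 4)
  expected <- (v >= q4$bin_edges[2]) + (v >= q4$bin_edges[3]) +
    (v >= q4$bin_edges[4])
  expect_equal(q4$codes, as.integer(expected))
  expect_equal(length(q4$bin_edges), 5)
  expect_true(all(diff(q4$bin_edges) > 0))

  # re-quantizing bin-centre values reproduces the same symbols
  centers <- (q4$bin_edges[-1] + q4$bin_edges[-5]) / 2
  expect_equal(quantize(centers, 4, bin_edges = q4$bin_edges)$codes, 0:3)

  # values beyond the percentile span clip into the end bins
  spiky <- c(rep(0:9, 20), -100, 100)
  qs <- quantize(spiky, levels = 10)
  expect_equal(qs$codes[length(spiky) - 1], 0L)
  expect_equal(qs$codes[length(spiky)], 9L)
  expect_error(quantize(v, levels = 1), ">= 2")
})

test_that("fuzzy Hamming distance grades mismatches and matches the loop oracle", {
  expect_equal(fuzzy_hamming(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(fuzzy_hamming(rep(0, 4), rep(2, 4)), 1.0)
  expect_equal(fuzzy_hamming(c(0, 1), c(1, 0)), 0.5)  # adjacent bins
  expect_error(fuzzy_hamming(1:3, 1:4), "length")
  set.seed(8)
  for (i in 1:10) {
    a <- sample(0:15, 40, replace = TRUE)
    b <- sample(0:15, 40, replace = TRUE)
    oracle <- mean(vapply(seq_along(a), function(j) {
      min(abs(a[j] - b[j]), 2) / 2
    }, numeric(1)))
    expect_equal(fuzzy_hamming(a, b), oracle)
  }
})

test_that("template matching equals exhaustive enumeration on short signals", {
  set.seed(4)
  params <- template_params(levels = 8, accept_threshold = 0.4,
                            length_scales = c(0.8, 1.0, 1.25))
  # structured signal: two embedded copies of a motif in noise
  motif <- sin(seq(0, pi, length.out = 40)) * 3
  x <- rnorm(300, 0, 0.3)
  x[51:90] <- x[51:90] + motif
  x[201:240] <- x[201:240] + motif
  ct <- signal_trace(x, 100)
  tmpl <- list(values = motif, rate_hz = 100, length_s = 0.4,
               polarity = "as_is")
  got <- match_template(tmpl, ct, params)
  want <- brute_force_match(tmpl, ct, params)
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$start_s, want$start_s)
  expect_equal(got$distance, want$distance, tolerance = 1e-12)
  expect_equal(got$scale, want$scale)

  # a template equal to an exact subsequence scores 0 at its own offset
  sub <- list(values = x[101:140], rate_hz = 100, length_s = 0.4,
              polarity = "as_is")
  hit <- match_template(sub, ct, template_params(accept_threshold = 0.3))
  self <- hit[abs(hit$start_s - 1.00) < 1e-9 & hit$scale == 1, ]
  expect_equal(nrow(self), 1)
  expect_equal(self$distance, 0)
})

test_that("matching a periodic signal finds minima at period multiples", {
  t <- (0:599) / 100
  x <- sin(2 * pi * t)                 # period 1 s
  ct <- signal_trace(x, 100)
  tmpl <- list(values = x[1:100], rate_hz = 100, length_s = 1,
               polarity = "as_is")
  cands <- match_template(tmpl, ct, template_params(accept_threshold = 0.2))
  # local distance minima sit at integer multiples of the period
  for (k in 0:5) {
    near <- cands[abs(cands$start_s - k) < 0.2, ]
    expect_gt(nrow(near), 0)
    expect_lte(abs(near$start_s[which.min(near$distance)] - k), 0.01 + 1e-9)
  }
})

test_that("cycle selection is greedy, feasible and maximal", {
  empty <- select_cycles(tibble::tibble(start_s = numeric(0),
                                        end_s = numeric(0),
                                        distance = numeric(0)), 0.1)
  expect_equal(nrow(empty), 0)

  two <- tibble::tibble(start_s = c(0, 2), end_s = c(1, 3),
                        distance = c(0.2, 0.1))
  two <- two[order(two$distance), ]
  expect_equal(nrow(select_cycles(two, 0.1)), 2)

  overlap <- tibble::tibble(start_s = c(0, 0.5), end_s = c(1, 1.5),
                            distance = c(0.1, 0.2))
  kept <- select_cycles(overlap, 0.1)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$score, 0.1)

  # enumeration oracle on random small candidate sets: the greedy pick is
  # feasible under dilation and maximal (no rejected candidate still fits)
  set.seed(13)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    st <- runif(n, 0, 5)
    cands <- tibble::tibble(start_s = st, end_s = st + runif(n, 0.3, 0.8),
                            distance = runif(n, 0, 0.3))
    cands <- cands[order(cands$distance, cands$start_s), ]
    sel <- select_cycles(cands, 0.1)
    subsets <- feasible_subsets(cands, 0.1)
    key <- function(s, e) paste(round(s, 9), round(e, 9), collapse = "|")
    sel_idx <- which(vapply(seq_len(nrow(cands)), function(i) {
      any(abs(cands$start_s[i] - sel$start_s) < 1e-12 &
            abs(cands$end_s[i] - sel$end_s) < 1e-12)
    }, logical(1)))
    is_feasible <- any(vapply(subsets, function(s) {
      length(s) == length(sel_idx) && all(sort(s) == sort(sel_idx))
    }, logical(1)))
    expect_true(is_feasible)
    # maximality: every candidate outside the selection conflicts with it
    for (i in setdiff(seq_len(nrow(cands)), sel_idx)) {
      conflict <- any(cands$start_s[i] - 0.1 < sel$end_s &
                        cands$end_s[i] + 0.1 > sel$start_s)
      expect_true(conflict)
    }
    # non-overlap invariant after refractory dilation
    if (nrow(sel) > 1) {
      expect_true(all(sel$start_s[-1] - 0.1 >= sel$end_s[-nrow(sel)]))
    }
  }
})

test_that("template refinement takes the pointwise median and flags empty input", {
  x <- rep(c(0, 0, 5, 5, 0, 0, 0, 0), 6)
  ct <- signal_trace(x, 100)
  tmpl <- list(values = x[1:8], rate_hz = 100, length_s = 0.08,
               polarity = "as_is")
  cyc <- select_cycles(tibble::tibble(
    start_s = c(0, 0.08, 0.16), end_s = c(0.08, 0.16, 0.24),
    distance = c(0, 0, 0)), 0)
  # identical matched instances: fixed point
  ref <- refine_template(tmpl, cyc, ct)
  expect_true(attr(ref, "refined"))
  expect_equal(ref$values, tmpl$values)

  # two level-shifted instances: median curve lies between them
  y <- c(1:10, 1:10 + 4)
  ct2 <- signal_trace(y, 100)
  cyc2 <- select_cycles(tibble::tibble(start_s = c(0, 0.1),
                                       end_s = c(0.1, 0.2),
                                       distance = c(0, 0)), 0)
  ref2 <- refine_template(list(values = 1:10, rate_hz = 100, length_s = 0.1,
                               polarity = "as_is"), cyc2, ct2)
  expect_equal(ref2$values, 1:10 + 2)

  none <- refine_template(tmpl, cyc[0, ], ct)
  expect_false(attr(none, "refined"))
  expect_equal(none$values, tmpl$values)
})
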