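# Fuzzy time-domain template matching: the few-shot core of the package.
#
# A swing-phase hint is turned into a template; the template is quantized
# into a small symbol alphabet, slid across the quantized recording at a
# grid of length scales, and scored with a graded ("fuzzy") Hamming
# distance. Candidates under an acceptance threshold are thinned to a
# non-overlapping cycle set, the template is re-estimated from the matched
# instances, and the loop repeats until the cycle boundaries stop moving.

#' Template-matching parameters
#'
#' @param levels Quantization alphabet size L (>= 2), default 16.
#' @param accept_threshold Maximum normalized fuzzy Hamming distance in
#'   (0, 1) for a candidate to be kept, default 0.25.
#' @param length_scales Multiset of template length scale factors tried at
#'   every offset, default `seq(0.8, 1.2, by = 0.05)`. The span covers the
#'   step-time variability seen across walking trials; the 5% step keeps
#'   the sharp heel-strike transient aligned within the window (a coarser
#'   10% grid demonstrably drops well-formed swing phases).
#' @param refractory_s Minimum gap enforced between selected cycles (s),
#'   default 0.10: two swing phases of one foot cannot be closer than a
#'   stance phase.
#' @param max_iter Maximum refinement iterations, default 20.
#' @return A list of class `template_params`.
#' @export
template_params <- function(levels = 16L, accept_threshold = 0.25,
                            length_scales = seq(0.8, 1.2, by = 0.05),
                            refractory_s = 0.10, max_iter = 20L) {
  if (levels < 2) stop("`levels` must be >= 2", call. = FALSE)
  if (accept_threshold <= 0 || accept_threshold >= 1) {
    stop("`accept_threshold` must lie in (0, 1)", call. = FALSE)
  }
  if (any(length_scales <= 0)) stop("length scales must be positive",
                                    call. = FALSE)
  structure(list(levels = as.integer(levels),
                 accept_threshold = accept_threshold,
                 length_scales = sort(length_scales),
                 refractory_s = refractory_s,
                 max_iter = as.integer(max_iter)),
            class = "template_params")
}

#' Quantize a signal into a symbol alphabet
#'
#' Uniform bins spanning the 1st-99th percentile of the values (samples
#' outside are clipped into the end bins), yielding per-sample integer
#' symbols `0 .. levels-1`. The percentile span makes the alphabet robust
#' to isolated spikes that would otherwise stretch the bins.
#'
#' @param x A [signal_trace()] or numeric vector.
#' @param levels Alphabet size (>= 2).
#' @param bin_edges Optional pre-computed edges (length `levels + 1`); when
#'   supplied, the percentile span is skipped and values are coded against
#'   these edges (used to code a template against a target recording's
#'   alphabet).
#' @return A list with `codes` (integer vector) and `bin_edges`.
#' @export
quantize <- function(x, levels = 16L, bin_edges = NULL) {
  v <- if (inherits(x, "signal_trace")) x$value else as.numeric(x)
  levels <- as.integer(levels)
  if (levels < 2) stop("`levels` must be >= 2", call. = FALSE)
  if (is.null(bin_edges)) {
    qs <- stats::quantile(v, c(0.01, 0.99), names = FALSE, type = 7)
    if (!is.finite(qs[1]) || qs[2] - qs[1] < .Machine$double.eps) {
      qs <- c(v[1] - 0.5, v[1] + 0.5)   # constant trace: one occupied bin
    }
    bin_edges <- seq(qs[1], qs[2], length.out = levels + 1L)
  }
  if (length(bin_edges) != levels + 1L || is.unsorted(bin_edges, strictly = TRUE)) {
    stop("`bin_edges` must be ", levels + 1L, " strictly ascending values",
         call. = FALSE)
  }
  interior <- bin_edges[-c(1L, levels + 1L)]
  codes <- findInterval(v, interior)   # clips into end bins automatically
  list(codes = as.integer(codes), bin_edges = bin_edges)
}

#' Fuzzy Hamming distance between symbol sequences
#'
#' Mean per-symbol mismatch cost with graded penalties:
#' `cost(i, j) = min(|i - j|, 2) / 2`, i.e. an exact match costs 0, adjacent
#' bins cost 1/2, and bins two or more apart cost 1. The grading is the
#' "fuzzy" softening of the plain Hamming distance: a signal sitting on a
#' bin boundary is not punished as a full mismatch.
#'
#' @param a,b Integer symbol vectors of equal length.
#' @return Normalized distance in \[0, 1\].
#' @export
fuzzy_hamming <- function(a, b) {
  if (length(a) != length(b)) {
    stop("symbol sequences differ in length", call. = FALSE)
  }
  if (!length(a)) return(0)
  mean(pmin(abs(as.numeric(a) - as.numeric(b)), 2) / 2)
}

# Resample a numeric vector to n points by linear interpolation over a
# shared normalized [0, 1] abscissa.
resample_to <- function(v, n) {
  if (length(v) == n) return(v)
  if (length(v) == 1L) return(rep(v, n))
  stats::approx(seq(0, 1, length.out = length(v)), v,
                xout = seq(0, 1, length.out = n))$y
}

# Build a template payload from real-valued conditioned samples.
new_template <- function(values, rate_hz, polarity = "as_is") {
  list(values = as.numeric(values), rate_hz = rate_hz,
       length_s = length(values) / rate_hz, polarity = polarity)
}

#' Slide a template across a trace
#'
#' For every length scale factor and every start offset (stride one
#' sample), the template is resampled to the scaled length, coded against
#' the trace's quantization alphabet, and compared with the window under
#' the fuzzy Hamming distance. All windows scoring below the acceptance
#' threshold are returned.
#'
#' @param template A template as built by [build_template()] (real-valued
#'   conditioned samples + rate).
#' @param x The conditioned [signal_trace()] to search.
#' @param params A [template_params()].
#' @param quant Optional precomputed [quantize()] result for `x`.
#' @return A tibble of candidates (`start_s`, `end_s`, `distance`, `scale`)
#'   sorted by distance then start time.
#' @export
match_template <- function(template, x, params = template_params(),
                           quant = NULL) {
  if (!length(template$values)) stop("empty template", call. = FALSE)
  rate <- trace_rate(x)
  if (is.null(quant)) quant <- quantize(x, params$levels)
  codes <- quant$codes
  n <- length(codes)
  out <- list()
  for (s in params$length_scales) {
    Ls <- max(2L, round(template$length_s * s * rate))
    if (Ls > n) next
    tq <- quantize(resample_to(template$values, Ls), params$levels,
                   bin_edges = quant$bin_edges)$codes
    W <- stats::embed(codes, Ls)[, Ls:1, drop = FALSE]
    D <- abs(sweep(W, 2, tq))
    dist <- rowMeans(pmin(D, 2) / 2)
    keep <- which(dist < params$accept_threshold)
    if (length(keep)) {
      start_s <- trace_t0(x) + (keep - 1L) / rate
      out[[length(out) + 1L]] <- tibble::tibble(
        start_s = start_s, end_s = start_s + Ls / rate,
        distance = dist[keep], scale = s)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                          distance = numeric(0), scale = numeric(0)))
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$distance, .data$start_s)
}

#' Thin match candidates to a non-overlapping cycle set
#'
#' Greedy best-first selection: candidates are taken in the order produced
#' by [match_template()] (distance ascending, ties by earlier start), and a
#' candidate is kept only if its interval, dilated by the refractory gap on
#' each side, intersects no already-kept interval. Deterministic, and
#' favours the best-matching instance of each swing phase.
#'
#' @param candidates Candidate tibble from [match_template()].
#' @param refractory_s Dilation applied to each side before the overlap
#'   test (s).
#' @param channel Channel label recorded on the result.
#' @param template_length_s Final template duration recorded on the result.
#' @return A tibble of class `cycle_set` (`start_s`, `end_s`, `score`),
#'   sorted by start time; `score` is the fuzzy Hamming distance.
#' @export
select_cycles <- function(candidates, refractory_s = 0.10, channel = "",
                          template_length_s = NA_real_) {
  ks <- numeric(0); ke <- numeric(0); kd <- numeric(0)
  if (nrow(candidates)) {
    for (i in seq_len(nrow(candidates))) {
      s <- candidates$start_s[i]; e <- candidates$end_s[i]
      if (!length(ks) ||
          all(s - refractory_s >= ke | e + refractory_s <= ks)) {
        ks <- c(ks, s); ke <- c(ke, e); kd <- c(kd, candidates$distance[i])
      }
    }
  }
  ord <- order(ks)
  out <- tibble::tibble(start_s = ks[ord], end_s = ke[ord], score = kd[ord])
  structure(out, class = c("cycle_set", class(tibble::tibble())),
            channel = channel, template_length_s = template_length_s)
}

#' Re-estimate a template from its matched cycles
#'
#' The matched instances are resampled to the median matched length and the
#' new template is their pointwise median — robust to a single bad match.
#' With no cycles the template is returned unchanged, flagged via the
#' `refined` attribute.
#'
#' @param template Current template payload.
#' @param cycles A `cycle_set` on `x`.
#' @param x The conditioned [signal_trace()] the cycles index into.
#' @return A new template payload; `attr(, "refined")` is `FALSE` when no
#'   cycles were available.
#' @export
refine_template <- function(template, cycles, x) {
  if (!nrow(cycles)) {
    attr(template, "refined") <- FALSE
    return(template)
  }
  rate <- trace_rate(x)
  inst <- lapply(seq_len(nrow(cycles)), function(i) {
    trace_window(x, cycles$start_s[i], cycles$end_s[i])
  })
  inst <- inst[lengths(inst) >= 2]
  if (!length(inst)) {
    attr(template, "refined") <- FALSE
    return(template)
  }
  med_len <- as.integer(round(stats::median(lengths(inst))))
  M <- vapply(inst, resample_to, numeric(med_len), n = med_len)
  new_vals <- apply(M, 1, stats::median)
  out <- new_template(new_vals, rate, polarity = template$polarity)
  attr(out, "refined") <- TRUE
  out
}
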