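# Unsupervised first-pass segmentation of a conditioned gait signal.
#
# A diagonal-covariance Gaussian hidden Markov model is fit by EM on a
# small per-sample feature vector; the Viterbi path provides candidate
# stance/swing state boundaries. This stage is advisory: its boundaries
# are presented alongside user hints, but the final partition always comes
# from the hint-driven template matcher.

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Centred moving average with reflect padding (odd window).
moving_stat <- function(x, w) {
  w <- as.integer(w)
  if (w %% 2 == 0) w <- w + 1L
  if (w <= 1) return(x)
  h <- (w - 1L) %/% 2L
  xp <- pad_reflect(x, h)
  y <- as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))
  y[(h + 1):(h + length(x))]
}

#' Per-sample features for unsupervised segmentation
#'
#' Computes, for every sample: the smoothed value (centred moving average
#' over `window_s`), the first difference (value change per sample), and
#' the windowed root-mean-square. Stance samples of a foot accelerometer
#' are near-constant and low-RMS; swing samples carry large transients, so
#' these three features separate the phases well.
#'
#' @param x A [signal_trace()].
#' @param window_s Feature window in seconds (>= 2 samples).
#' @return A tibble with columns `time_s`, `smooth`, `diff`, `rms`.
#' @export
extract_features <- function(x, window_s = 0.1) {
  w <- round(window_s * trace_rate(x))
  if (w < 2) stop("feature window shorter than 2 samples", call. = FALSE)
  if (w > nrow(x)) stop("feature window longer than trace", call. = FALSE)
  v <- x$value
  sm <- moving_stat(v, w)
  d1 <- c(0, diff(v))
  rms <- sqrt(pmax(moving_stat(v^2, w), 0))
  tibble::tibble(time_s = x$time_s, smooth = sm, diff = d1, rms = rms)
}

# log N(x | mu, var) for a feature matrix under diagonal covariance
ghmm_logdens <- function(X, mu, var) {
  n <- nrow(X); K <- nrow(mu)
  out <- matrix(0, n, K)
  for (k in seq_len(K)) {
    out[, k] <- rowSums(-0.5 * (log(2 * pi * var[k, ])[col(X)] +
                                  (X - mu[k, ][col(X)])^2 / var[k, ][col(X)]))
  }
  out
}

# Scaled forward-backward. Returns log-likelihood, gamma, xi sums.
ghmm_estep <- function(logB, logpi, logA) {
  n <- nrow(logB); K <- ncol(logB)
  la <- matrix(-Inf, n, K)
  la[1, ] <- logpi + logB[1, ]
  for (t in 2:n) {
    for (k in seq_len(K)) {
      la[t, k] <- log_sum_exp(la[t - 1, ] + logA[, k]) + logB[t, k]
    }
  }
  ll <- log_sum_exp(la[n, ])
  lb <- matrix(0, n, K)
  for (t in (n - 1):1) {
    for (k in seq_len(K)) {
      lb[t, k] <- log_sum_exp(logA[k, ] + logB[t + 1, ] + lb[t + 1, ])
    }
  }
  lgamma_ <- la + lb - ll
  gamma <- exp(lgamma_)
  xi_sum <- matrix(0, K, K)
  for (t in seq_len(n - 1)) {
    lx <- outer(la[t, ], logB[t + 1, ] + lb[t + 1, ], "+") + logA - ll
    xi_sum <- xi_sum + exp(lx)
  }
  list(ll = ll, gamma = gamma, xi_sum = xi_sum)
}

log_sum_exp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

ghmm_viterbi <- function(logB, logpi, logA) {
  n <- nrow(logB); K <- ncol(logB)
  delta <- matrix(-Inf, n, K)
  psi <- matrix(0L, n, K)
  delta[1, ] <- logpi + logB[1, ]
  for (t in 2:n) {
    for (k in seq_len(K)) {
      sc <- delta[t - 1, ] + logA[, k]
      psi[t, k] <- which.max(sc)
      delta[t, k] <- sc[psi[t, k]] + logB[t, k]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

ghmm_fit_once <- function(X, K, max_iter, tol) {
  n <- nrow(X); d <- ncol(X)
  km <- tryCatch(stats::kmeans(X, centers = K, nstart = 1, iter.max = 30),
                 error = function(e) NULL)
  if (is.null(km)) {
    idx <- sample.int(n, K)
    mu <- X[idx, , drop = FALSE]
    lab <- max.col(-as.matrix(stats::dist(rbind(mu, X)))[-(1:K), 1:K,
                                                         drop = FALSE])
  } else {
    mu <- km$centers
    lab <- km$cluster
  }
  var <- matrix(0, K, d)
  gvar <- apply(X, 2, stats::var)
  gvar[!is.finite(gvar) | gvar <= 0] <- 1
  for (k in seq_len(K)) {
    xk <- X[lab == k, , drop = FALSE]
    v <- if (nrow(xk) > 1) apply(xk, 2, stats::var) else gvar
    v[!is.finite(v) | v < 1e-6] <- pmax(gvar * 1e-3, 1e-6)[!is.finite(v) | v < 1e-6]
    var[k, ] <- pmax(v, 1e-8)
  }
  A <- matrix(0.1 / max(K - 1, 1), K, K); diag(A) <- 0.9
  pi0 <- rep(1 / K, K)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  for (it in seq_len(max_iter)) {
    logB <- ghmm_logdens(X, mu, var)
    es <- ghmm_estep(logB, log(pi0), log(A))
    ll_trace <- c(ll_trace, es$ll)
    g <- es$gamma
    Nk <- colSums(g)
    Nk[Nk < 1e-10] <- 1e-10
    mu <- (t(g) %*% X) / Nk
    for (k in seq_len(K)) {
      dev <- sweep(X, 2, mu[k, ])
      var[k, ] <- pmax(colSums(g[, k] * dev^2) / Nk[k], 1e-8)
    }
    A <- es$xi_sum / rowSums(es$xi_sum)
    A[!is.finite(A)] <- 1 / K
    A <- pmax(A, 1e-12); A <- A / rowSums(A)
    pi0 <- pmax(g[1, ], 1e-12); pi0 <- pi0 / sum(pi0)
    if (is.finite(ll_prev) &&
        abs(es$ll - ll_prev) < tol * (abs(ll_prev) + 1e-12)) break
    ll_prev <- es$ll
  }
  logB <- ghmm_logdens(X, mu, var)
  path <- ghmm_viterbi(logB, log(pi0), log(A))
  list(ll = ll_trace[length(ll_trace)], ll_trace = ll_trace, path = path)
}

#' Unsupervised HMM segmentation of a signal trace
#'
#' Fits a diagonal-covariance Gaussian hidden Markov model to the
#' [extract_features()] sequence by expectation-maximization (multiple
#' seeded restarts, best log-likelihood kept) and decodes the most probable
#' state path. Boundaries are reported where the decoded label changes.
#' Deterministic given `seed`.
#'
#' @param x A [signal_trace()].
#' @param n_states Number of hidden states (2-16), default 6.
#' @param seed Integer RNG seed for restarts.
#' @param restarts Number of EM restarts, default 10.
#' @param window_s Feature window (s), default 0.1.
#' @param max_iter,tol EM stopping rule: at most `max_iter` iterations or
#'   relative log-likelihood change below `tol`.
#' @return A list of class `gait_segmentation`: `state_seq` (0-based
#'   labels), `boundaries_s`, `n_states`, `log_likelihood`, `loglik_trace`.
#' @export
segment_unsupervised <- function(x, n_states = 6L, seed = 1L, restarts = 10L,
                                 window_s = 0.1, max_iter = 200L, tol = 1e-4) {
  n_states <- as.integer(n_states)
  if (n_states < 2 || n_states > 16) {
    stop("`n_states` must be in 2..16", call. = FALSE)
  }
  if (nrow(x) < 10 * n_states) {
    stop("trace too short for requested state count", call. = FALSE)
  }
  feats <- extract_features(x, window_s)
  X <- as.matrix(feats[, c("smooth", "diff", "rms")])
  sds <- apply(X, 2, stats::sd)
  # degenerate (near-constant) input: a single state explains everything
  if (all(sds < 1e-12 * max(1, max(abs(X))))) {
    res <- list(state_seq = rep(0L, nrow(x)), boundaries_s = numeric(0),
                n_states = n_states, log_likelihood = NA_real_,
                loglik_trace = numeric(0), rate_hz = trace_rate(x))
    class(res) <- "gait_segmentation"
    return(res)
  }
  sds[sds < 1e-12] <- 1
  X <- sweep(sweep(X, 2, colMeans(X)), 2, sds, "/")
  best <- NULL
  with_local_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- tryCatch(ghmm_fit_once(X, n_states, max_iter, tol),
                      error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$ll > best$ll)) best <- fit
    }
  })
  if (is.null(best)) {
    stop("EM failed to produce a fit in any restart", call. = FALSE)
  }
  path0 <- as.integer(best$path - 1L)
  chg <- which(diff(path0) != 0)
  res <- list(state_seq = path0,
              boundaries_s = x$time_s[chg + 1L],
              n_states = n_states,
              log_likelihood = best$ll,
              loglik_trace = best$ll_trace,
              rate_hz = trace_rate(x))
  class(res) <- "gait_segmentation"
  res
}

#' @export
print.gait_segmentation <- function(x, ...) {
  cat(sprintf("<gait_segmentation> %d samples, %d states, %d boundaries, logLik %.2f\n",
              length(x$state_seq), x$n_states, length(x$boundaries_s),
              x$log_likelihood))
  invisible(x)
}

#' @rdname tidy.gait_error_report
#' @method tidy gait_segmentation
#' @export
tidy.gait_segmentation <- function(x, ...) {
  tibble::tibble(
    sample = seq_along(x$state_seq) - 1L,
    time_s = (seq_along(x$state_seq) - 1L) / x$rate_hz,
    state = x$state_seq
  )
}
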