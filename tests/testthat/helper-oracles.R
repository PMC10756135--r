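# Independent reference implementations used as oracles.  Each recomputes
# the quantity from scratch, without the package's streaming/fast paths.

# Offline detector: per sample, window statistics recomputed from scratch
# over the trailing M samples, then the state machine replayed step by step.
detect_oracle <- function(x, M, gain = 1.1, warmup_frac = 0.1) {
  warm <- ceiling(warmup_frac * M)
  st <- detector_init()
  rows <- list()
  for (i in seq_along(x)) {
    g <- if (i >= warm) {
      w <- x[max(1L, i - M + 1L):i]
      dynamic_gradient(w, gain)$gradient
    } else {
      Inf  # warm-up: extrema tracked, emission suppressed
    }
    r <- detector_step(st, i - 1L, x[i], g)
    st <- r$state
    if (!is.null(r$event)) {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = r$event$kind, index = r$event$index, value = r$event$value)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(kind = character(), index = integer(),
                      value = numeric()))
  }
  do.call(rbind, rows)
}

# Naive O(N*n) causal convolution.
conv_oracle <- function(x, b) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_len(min(i, length(b)))) {
      acc <- acc + b[k] * x[i - k + 1]
    }
    y[i] <- acc
  }
  y
}

# Exhaustive non-crossing assignment: maximize the number of pairs, then
# minimize total lag, with lags restricted to (0, max_lag].  Recursive with
# memoization over (i, j); fine for the small instances used in tests.
pair_oracle <- function(idx1, idx2, max_lag) {
  n1 <- length(idx1)
  n2 <- length(idx2)
  memo <- new.env(hash = TRUE)
  best <- function(i, j) {
    if (i > n1 || j > n2) return(list(count = 0, lag = 0, pairs = NULL))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    skip1 <- best(i + 1, j)
    skip2 <- best(i, j + 1)
    res <- if (skip1$count > skip2$count ||
               (skip1$count == skip2$count && skip1$lag <= skip2$lag)) {
      skip1
    } else {
      skip2
    }
    lag <- idx2[j] - idx1[i]
    if (lag > 0 && lag <= max_lag) {
      take <- best(i + 1, j + 1)
      cand <- list(count = take$count + 1, lag = take$lag + lag,
                   pairs = rbind(c(i, j), take$pairs))
      if (cand$count > res$count ||
          (cand$count == res$count && cand$lag < res$lag)) {
        res <- cand
      }
    }
    memo[[key]] <- res
    res
  }
  best(1, 1)
}

# Sort-based median.
median_oracle <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Noise-free dual-channel recording under the stated study conditions.
quiet_config <- function(heart_rate = 60, duration = 30, fs = 10000,
                         ptt_true = 0.005, ...) {
  synth_config(heart_rate = heart_rate, duration = duration, fs = fs,
               ptt_true = ptt_true, amplitude_jitter = 0,
               baseline_wander = list(amplitude = 0, freq = 0.3),
               noise_sd = 0, ...)
}
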