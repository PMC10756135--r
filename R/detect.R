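#' Dynamic-gradient threshold from a signal window
#'
#' The adaptive hysteresis threshold governing peak/trough emission:
#' `gradient = RMS * (CV / 100) * gain`, where RMS is the window's root mean
#' square amplitude and CV (in percent) is `100 * sd / |mean|` with the
#' uncentered window variance `sum((x - mean)^2) / M`.  A flat window has
#' zero dispersion and hence zero gradient; a window with zero mean
#' magnitude is treated as flat (CV defined as 0).  The threshold scales
#' linearly with the signal, which makes detection invariant to amplitude
#' re-scaling.
#'
#' @param x Numeric window of samples (the trailing `M` samples in the
#'   streaming detector).
#' @param gain Dimensionless threshold gain (default 1.1; raising it trades
#'   sensitivity for fewer false positives on low-SNR signals).
#' @return A list with `mean`, `rms`, `sd`, `cv` (percent) and `gradient`.
#' @examples
#' dynamic_gradient(c(0, 0, 3, 3))$gradient  # sqrt(4.5) * 1.1
#' @export
dynamic_gradient <- function(x, gain = 1.1) {
  if (length(x) < 1L) stop("window must be non-empty", call. = FALSE)
  if (gain <= 0) stop("`gain` must be > 0", call. = FALSE)
  m <- length(x)
  s <- sum(x)
  s2 <- sum(x * x)
  mu <- s / m
  ms <- s2 / m
  v <- max(ms - mu * mu, 0)
  sdev <- sqrt(v)
  rms <- sqrt(max(ms, 0))
  am <- abs(mu)
  cv <- if (am > 0) 100 * sdev / am else 0
  list(mean = mu, rms = rms, sd = sdev, cv = cv,
       gradient = rms * (cv / 100) * gain)
}

#' Initialize the peak/trough detector state machine
#'
#' The machine retains only the running local maximum and minimum (index and
#' value) and an emission flag; its size never depends on how many samples
#' have been seen.  Initial extrema are -Inf/+Inf and the machine starts in
#' emission state (looking for a peak), so the first excursion registers
#' correctly regardless of signal polarity.
#'
#' @return A list with `local_max`, `local_min` (each `list(index, value)`)
#'   and `is_emission`.
#' @export
detector_init <- function() {
  list(local_max = list(index = NA_integer_, value = -Inf),
       local_min = list(index = NA_integer_, value = Inf),
       is_emission = TRUE, last_index = -Inf)
}

#' Advance the detector by one sample
#'
#' One step of the constant-memory local-maximum/minimum state machine.
#' The running extrema are updated first (strict inequalities, so plateaus
#' keep the first sample's index).  Then, in emission state, a peak — the
#' stored local maximum — is emitted exactly when the value falls below
#' `local_max - gradient`, after which the local minimum is reset to the
#' local maximum; out of emission state, a trough — the stored local minimum
#' — is emitted exactly when the value rises above `local_min + gradient`,
#' after which the local maximum is reset to the local minimum.  Emitted
#' kinds therefore strictly alternate.
#'
#' @param state Detector state from [detector_init()] or a previous step.
#' @param index 0-based sample index (must be fed in increasing order).
#' @param value Sample value.
#' @param gradient Current threshold from [dynamic_gradient()].
#' @return A list with `state` (updated) and `event` (`NULL`, or a list with
#'   `kind` (`"peak"`/`"trough"`), `index`, `value`).
#' @examples
#' st <- detector_init()
#' for (i in seq_along(c(0, 1, 2, 3, 2.9, 2.5, 1))) {
#'   r <- detector_step(st, i - 1, c(0, 1, 2, 3, 2.9, 2.5, 1)[i], gradient = 1)
#'   st <- r$state
#'   if (!is.null(r$event)) print(r$event)
#' }
#' @export
detector_step <- function(state, index, value, gradient) {
  lm <- state$local_max
  ln <- state$local_min
  if (index <= state$last_index) {
    stop("sample indices must be strictly increasing", call. = FALSE)
  }
  if (value > lm$value) lm <- list(index = index, value = value)
  if (value < ln$value) ln <- list(index = index, value = value)
  event <- NULL
  em <- state$is_emission
  if (em && value < lm$value - gradient) {
    em <- FALSE
    event <- list(kind = "peak", index = lm$index, value = lm$value)
    ln <- lm
  } else if (!em && value > ln$value + gradient) {
    em <- TRUE
    event <- list(kind = "trough", index = ln$index, value = ln$value)
    lm <- ln
  }
  list(state = list(local_max = lm, local_min = ln, is_emission = em,
                    last_index = index),
       event = event)
}

#' Detect pulse peaks and troughs with the dynamic-gradient algorithm
#'
#' Single streaming pass over the trace.  At each sample the threshold is
#' recomputed from the trailing `window` samples with constant-size running
#' accumulators (sum and sum of squares plus the eviction stream — the
#' retained state is O(1) in the trace length), and the state machine of
#' [detector_step()] is advanced.  No events are emitted until
#' `warmup_frac * window` samples have been observed; until a full window
#' has been seen the statistics use all samples so far.
#'
#' @param trace A [signal_trace()]; detection statistics are computed on
#'   this same trace (feed it the FIR-filtered signal for the device chain).
#' @param window Threshold window size M in samples (default: the sampling
#'   rate, i.e. one second of signal; half that is the recommended setting
#'   for arrhythmic subjects).
#' @param gain Threshold gain, default 1.1.
#' @param warmup_frac Fraction of `window` that must elapse before events
#'   may be emitted (default 0.1).
#' @return A data.frame with columns `kind` (`"peak"`/`"trough"`), `index`
#'   (0-based), `time_s` and `value`; attribute `detector_state` carries the
#'   fixed-length final accumulator vector.
#' @examples
#' tr <- generate_dual_channel(synth_config(duration = 10, noise_sd = 0,
#'   amplitude_jitter = 0, baseline_wander = list(amplitude = 0, freq = 0.3)))
#' ev <- detect_features(tr$ch1)
#' table(ev$kind)
#' @export
detect_features <- function(trace, window = NULL, gain = 1.1,
                            warmup_frac = 0.1) {
  if (!inherits(trace, "signal_trace")) {
    stop("`trace` must be a signal_trace", call. = FALSE)
  }
  if (is.null(window)) window <- as.integer(round(trace$fs))
  if (window < 1) stop("`window` must be >= 1 sample", call. = FALSE)
  if (gain <= 0) stop("`gain` must be > 0", call. = FALSE)
  res <- detect_core(trace$x, as.integer(window), gain, warmup_frac)
  ev <- data.frame(
    kind = ifelse(res$kind > 0, "peak", "trough"),
    index = res$index,
    time_s = res$index / trace$fs,
    value = res$value,
    stringsAsFactors = FALSE
  )
  attr(ev, "detector_state") <- res$state
  ev
}
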