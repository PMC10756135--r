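#' Configuration for the dual-channel pulse synthesizer
#'
#' Describes a quasi-periodic radial pulse recording as captured by two
#' sensors a few centimeters apart: a beat train of asymmetric gamma-shaped
#' pulses (fast rise, slow decay, unit peak), a fixed inter-channel transit
#' delay, per-beat amplitude variability, sinusoidal baseline wander and
#' additive white noise.  The second channel is the first channel's clean
#' beat train delayed by `round(ptt_true * fs)` samples; noise and wander are
#' drawn independently per channel, so the transit delay is carried by the
#' physiological waveform only.
#'
#' @param heart_rate Beats per minute in `[36, 300]`.
#' @param duration Recording length in seconds (> 0).
#' @param fs Sampling rate in Hz (default 10000).
#' @param ptt_true True inter-channel transit time in seconds; must be
#'   non-negative and smaller than the beat interval.
#' @param pulse_shape List with `time_to_peak` (s) and `shape`
#'   (dimensionless asymmetry of the gamma bump).  The template is
#'   \eqn{g(\tau) = (\tau/t_p)^a \exp(a (1 - \tau/t_p))}, normalized to unit
#'   peak at \eqn{\tau = t_p}, truncated at `min(6 * time_to_peak, beat
#'   interval)`.
#' @param amplitude Peak amplitude in mV per channel (length-2 vector).
#' @param amplitude_jitter Fractional standard deviation of per-beat
#'   amplitude (shared across channels; a beat's amplitude is the same at
#'   both sensors).
#' @param baseline_wander List with `amplitude` (mV) and `freq` (Hz) of a
#'   sinusoidal baseline drift, random phase per channel.
#' @param noise_sd Additive white noise standard deviation in mV per channel.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   traces.
#' @param beat_times Optional explicit beat onset times in seconds
#'   (overrides `heart_rate`; used e.g. for arrhythmic trains).
#'
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(heart_rate = 60, duration = 30, fs = 10000,
                         ptt_true = 0.005,
                         pulse_shape = list(time_to_peak = 0.12, shape = 2),
                         amplitude = c(300, 300),
                         amplitude_jitter = 0.02,
                         baseline_wander = list(amplitude = 20, freq = 0.3),
                         noise_sd = 5,
                         seed = NULL,
                         beat_times = NULL) {
  stopifnot_scalar_pos(fs, "fs")
  stopifnot_scalar_pos(duration, "duration")
  if (heart_rate < 36 || heart_rate > 300) {
    stop("`heart_rate` must lie in [36, 300] bpm", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (amplitude_jitter < 0) stop("`amplitude_jitter` must be >= 0", call. = FALSE)
  if (length(amplitude) == 1L) amplitude <- rep(amplitude, 2L)
  if (any(amplitude <= 0)) stop("`amplitude` must be positive", call. = FALSE)
  beat_interval <- if (is.null(beat_times)) 60 / heart_rate else min(diff(beat_times))
  if (ptt_true < 0 || ptt_true >= beat_interval) {
    stop(sprintf(
      "`ptt_true` (%g s) must lie in [0, beat interval = %g s): channel pairing would be ambiguous",
      ptt_true, beat_interval), call. = FALSE)
  }
  stopifnot_scalar_pos(pulse_shape$time_to_peak, "pulse_shape$time_to_peak")
  stopifnot_scalar_pos(pulse_shape$shape, "pulse_shape$shape")
  structure(
    list(heart_rate = heart_rate, duration = duration, fs = fs,
         ptt_true = ptt_true, pulse_shape = pulse_shape,
         amplitude = amplitude, amplitude_jitter = amplitude_jitter,
         baseline_wander = baseline_wander, noise_sd = noise_sd,
         seed = seed, beat_times = beat_times),
    class = "synth_config"
  )
}

# Unit-peak gamma bump: fast rise to tau = tp, slow decay.
pulse_template <- function(tau, tp, a) {
  g <- numeric(length(tau))
  pos <- tau > 0
  u <- tau[pos] / tp
  g[pos] <- u^a * exp(a * (1 - u))
  g
}

#' Generate a dual-channel synthetic pulse recording
#'
#' Builds the clean beat train on channel 1, shifts it by an integer number
#' of samples `round(ptt_true * fs)` to form channel 2 (the transit-time
#' resolution of the downstream chain is one sample period, so the ground
#' truth is quantized to the grid), then adds per-channel baseline wander and
#' noise.  A beat is included only if its template support ends inside the
#' recording; the last partial beat is truncated, not wrapped.
#'
#' @param config A [synth_config()] object.
#' @return A list of class `dual_trace` with elements `ch1`, `ch2`
#'   ([signal_trace()] objects of identical length `round(duration * fs)`),
#'   `beat_times` (onset times, s), `delay_samples`
#'   (`round(ptt_true * fs)`), and `fs`.
#' @examples
#' tr <- generate_dual_channel(synth_config(duration = 5, noise_sd = 0,
#'   amplitude_jitter = 0, baseline_wander = list(amplitude = 0, freq = 0.3)))
#' length(tr$beat_times)
#' @export
generate_dual_channel <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop("`config` must be a synth_config object", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$fs
  n <- round(config$duration * fs)
  t <- (seq_len(n) - 1) / fs
  tp <- config$pulse_shape$time_to_peak
  a <- config$pulse_shape$shape

  if (is.null(config$beat_times)) {
    period <- 60 / config$heart_rate
    support <- min(6 * tp, period)
    k_max <- floor((config$duration - support) / period + 1e-12)
    beats <- if (k_max < 0) numeric(0) else (0:k_max) * period
  } else {
    support <- min(6 * tp, min(diff(config$beat_times)))
    beats <- config$beat_times
    beats <- beats[beats + support <= config$duration + 1e-12]
  }
  if (length(beats) < 1L) {
    stop("no complete beat fits inside the requested duration", call. = FALSE)
  }

  amp_jit <- 1 + config$amplitude_jitter * rnorm(length(beats))
  amp_jit <- pmax(amp_jit, 0.05)  # amplitudes stay positive

  clean <- numeric(n)
  for (b in seq_along(beats)) {
    i0 <- floor(beats[b] * fs) + 1L
    i1 <- min(n, ceiling((beats[b] + support) * fs) + 1L)
    idx <- i0:i1
    clean[idx] <- clean[idx] +
      amp_jit[b] * pulse_template(t[idx] - beats[b], tp, a)
  }

  d <- as.integer(round(config$ptt_true * fs))
  clean2 <- numeric(n)
  if (d < n) clean2[(d + 1L):n] <- clean[seq_len(n - d)]

  bw <- config$baseline_wander
  make_channel <- function(cl, amp, label) {
    x <- amp * cl
    if (!is.null(bw) && bw$amplitude > 0) {
      phase <- runif(1, 0, 2 * pi)
      x <- x + bw$amplitude * sin(2 * pi * bw$freq * t + phase)
    }
    if (config$noise_sd > 0) x <- x + rnorm(n, sd = config$noise_sd)
    signal_trace(x, fs, channel = label)
  }
  ch1 <- make_channel(clean, config$amplitude[1], "ch1")
  ch2 <- make_channel(clean2, config$amplitude[2], "ch2")

  structure(list(ch1 = ch1, ch2 = ch2, beat_times = beats,
                 delay_samples = d, fs = fs),
            class = "dual_trace")
}

#' @export
print.dual_trace <- function(x, ...) {
  cat(sprintf("<dual_trace> %d beats, %d samples/channel @ %g Hz, delay %d samples\n",
              length(x$beat_times), length(x$ch1$x), x$fs, x$delay_samples))
  invisible(x)
}

#' Construct a synthetic subject with known hemodynamic ground truth
#'
#' Given a true mean arterial pressure and artery geometry, derives the pulse
#' wave velocity the forward Moens-Korteweg model implies and the transit
#' time over the sensor separation `L`.  True SBP/DBP are derived from MAP
#' with the device's split convention so the full chain has a consistent
#' ground truth.
#'
#' @param map_true True mean arterial pressure in mmHg (> 0).
#' @param artery An [artery_params()] object.
#' @param L Sensor separation in meters (default 0.03).
#' @param k Split factor used for the true SBP/DBP, default 0.76.
#' @return An object of class `synthetic_subject` with fields `artery`,
#'   `true_map`, `true_sbp`, `true_dbp`, `derived_pwv` (m/s) and
#'   `derived_ptt` (s).
#' @examples
#' generate_subject(90, artery_params())
#' @export
generate_subject <- function(map_true, artery = artery_params(), L = 0.03,
                             k = 0.76) {
  stopifnot_scalar_pos(map_true, "map_true")
  stopifnot_scalar_pos(L, "L")
  artery <- as_artery(artery)
  pwv <- mk_forward(map_true, artery)
  split <- split_map(map_true, k = k)
  structure(
    list(artery = artery, true_map = map_true, true_sbp = split$sbp,
         true_dbp = split$dbp, derived_pwv = pwv, derived_ptt = L / pwv,
         L = L),
    class = "synthetic_subject"
  )
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf(
    "<synthetic_subject> MAP %.1f (SBP %.1f / DBP %.1f) mmHg, PWV %.2f m/s, PTT %.3f ms over %g cm\n",
    x$true_map, x$true_sbp, x$true_dbp, x$derived_pwv,
    x$derived_ptt * 1e3, x$L * 1e2))
  invisible(x)
}

#' Default physiologic parameter ranges for a synthetic cohort
#'
#' Radial-artery lumen diameter 2.0-3.0 mm, wall thickness 0.2-0.4 mm, MAP
#' 70-110 mmHg: plausible adult values for the vessel the sensors sit on.
#'
#' @return Named list of length-2 numeric ranges `D` (m), `h` (m), `map`
#'   (mmHg).
#' @export
cohort_ranges <- function() {
  list(D = c(2.0e-3, 3.0e-3), h = c(0.2e-3, 0.4e-3), map = c(70, 110))
}

#' Generate a synthetic subject cohort
#'
#' Draws `n` subjects with independent uniform artery geometry and true MAP
#' inside `ranges`, reproducibly given `seed`.
#'
#' @param n Number of subjects (>= 1).
#' @param ranges Named list of ranges as in [cohort_ranges()]; each must be a
#'   positive, strictly increasing length-2 vector (a degenerate range
#'   `c(v, v)` fixes the value).
#' @param seed Integer seed.
#' @param L Sensor separation in meters.
#' @param k Split factor for the true SBP/DBP.
#' @return A list of [generate_subject()] objects, class `synthetic_cohort`.
#' @examples
#' coh <- generate_cohort(4, seed = 1)
#' sapply(coh, function(s) s$true_map)
#' @export
generate_cohort <- function(n, ranges = cohort_ranges(), seed = NULL,
                            L = 0.03, k = 0.76) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be >= 1", call. = FALSE)
  }
  for (nm in c("D", "h", "map")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2L || any(r <= 0) || r[1] > r[2]) {
      stop(sprintf("range `%s` must be positive and ordered", nm),
           call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    D <- runif(1, ranges$D[1], ranges$D[2])
    h <- runif(1, ranges$h[1], ranges$h[2])
    map <- runif(1, ranges$map[1], ranges$map[2])
    subjects[[i]] <- generate_subject(map, artery_params(D = D, h = h),
                                      L = L, k = k)
  }
  structure(subjects, class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  maps <- vapply(x, function(s) s$true_map, numeric(1))
  cat(sprintf("<synthetic_cohort> %d subjects, MAP %.1f-%.1f mmHg\n",
              length(x), min(maps), max(maps)))
  invisible(x)
}
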