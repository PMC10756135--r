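#' End-to-end run configuration
#'
#' Bundles and cross-validates the parameters of every pipeline stage:
#' FIR filter spec, detector window and gain, pairing mode and bound,
#' sensor separation, artery parameters and split factor.  All lengths are
#' meters, times seconds, pressures mmHg; sample indices are 0-based.
#'
#' @param fs Sampling rate in Hz.
#' @param fir A [fir_spec()]; its `fs` must match `fs`.
#' @param window Detector window M in samples (default `fs`).
#' @param gain Detector threshold gain (default 1.1).
#' @param mode Pairing mode `"pp"` or `"ff"`.
#' @param max_ptt Pairing bound in seconds (default 0.05).
#' @param L Sensor separation in meters (default 0.03).
#' @param artery An [artery_params()] object.
#' @param k MAP split factor (default 0.76).
#' @param split `"printed"` or `"consistent"` (see [split_map()]).
#' @return An object of class `run_config`.
#' @export
run_config <- function(fs = 10000, fir = fir_spec(fs = fs),
                       window = NULL, gain = 1.1,
                       mode = c("pp", "ff"), max_ptt = 0.05, L = 0.03,
                       artery = artery_params(), k = 0.76,
                       split = c("printed", "consistent")) {
  mode <- match.arg(mode)
  split <- match.arg(split)
  stopifnot_scalar_pos(fs, "fs")
  if (!inherits(fir, "fir_spec")) stop("`fir` must be a fir_spec", call. = FALSE)
  if (abs(fir$fs - fs) > 1e-9 * fs) {
    stop(sprintf("filter spec fs (%g) does not match run fs (%g)", fir$fs, fs),
         call. = FALSE)
  }
  if (is.null(window)) window <- as.integer(round(fs))
  if (window < 1) stop("`window` must be >= 1", call. = FALSE)
  if (gain <= 0) stop("`gain` must be > 0", call. = FALSE)
  if (max_ptt <= 0) stop("`max_ptt` must be > 0", call. = FALSE)
  stopifnot_scalar_pos(L, "L")
  artery <- as_artery(artery)
  if (k <= 0 || k >= 1) stop("`k` must lie in (0, 1)", call. = FALSE)
  structure(list(fs = fs, fir = fir, window = as.integer(window), gain = gain,
                 mode = mode, max_ptt = max_ptt, L = L, artery = artery,
                 k = k, split = split),
            class = "run_config")
}

#' Write a dual-channel recording as CSV
#'
#' Plain-text interchange format with header `time_s,ch1_mv,ch2_mv`.
#'
#' @param path Output file path.
#' @param ch1,ch2 [signal_trace()] objects of equal length and rate.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(path, ch1, ch2) {
  if (length(ch1$x) != length(ch2$x) || abs(ch1$fs - ch2$fs) > 0) {
    stop("channels must share length and sampling rate", call. = FALSE)
  }
  df <- data.frame(time_s = (seq_along(ch1$x) - 1) / ch1$fs,
                   ch1_mv = ch1$x, ch2_mv = ch2$x)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a dual-channel recording from CSV
#'
#' Expects the header `time_s,ch1_mv,ch2_mv`, strictly increasing uniform
#' time stamps and no missing values.  The sampling rate is inferred from
#' the median time step and, when `fs` is supplied, cross-checked against
#' it to within 0.1 %.
#'
#' @param path CSV file path.
#' @param fs Optional expected sampling rate in Hz.
#' @return A list with `ch1` and `ch2` ([signal_trace()]) and `fs`.
#' @export
read_signal_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path)
  need <- c("time_s", "ch1_mv", "ch2_mv")
  if (!identical(names(df)[seq_along(need)], need)) {
    stop(sprintf("expected columns %s, found %s",
                 paste(need, collapse = ","),
                 paste(names(df), collapse = ",")), call. = FALSE)
  }
  if (nrow(df) < 2L) stop("signal file holds fewer than 2 samples", call. = FALSE)
  if (anyNA(df[need])) stop("signal file contains NA values", call. = FALSE)
  dt <- diff(df$time_s)
  med <- median(dt)
  if (med <= 0 || any(dt <= 0)) {
    stop("time stamps must be strictly increasing (duplicated or reversed time found)",
         call. = FALSE)
  }
  if (max(abs(dt - med)) > 1e-4 * med) {
    stop("non-uniform sampling: time steps deviate from the median step",
         call. = FALSE)
  }
  fs_inferred <- 1 / med
  if (!is.null(fs) && abs(fs_inferred - fs) > 1e-3 * fs) {
    stop(sprintf("sampling rate mismatch: file implies %.6g Hz, config says %.6g Hz",
                 fs_inferred, fs), call. = FALSE)
  }
  list(ch1 = signal_trace(df$ch1_mv, fs_inferred, channel = "ch1"),
       ch2 = signal_trace(df$ch2_mv, fs_inferred, channel = "ch2"),
       fs = fs_inferred)
}

#' Run the full measurement pipeline on a dual-channel recording
#'
#' Stages, in order: FIR bandpass on both channels (same coefficients, so
#' the shared group delay cancels in transit times); dynamic-gradient
#' feature detection per channel; cross-channel beat pairing; beat-wise
#' transit time and pulse wave velocity; median aggregation; Moens-Korteweg
#' inversion and MAP split.  Each stage's parameters and counts are logged.
#' Fewer than 3 paired beats is an error (the median would be unreliable).
#'
#' @param config A [run_config()] object.
#' @param signals A list with `ch1` and `ch2` [signal_trace()] objects (as
#'   from [generate_dual_channel()] or [read_signal_csv()]).
#' @return An object of class `bp_run`: list with `bp` ([estimate_bp()]
#'   result), `pwv` (beat-wise table), `median_pwv`, `events` (per channel)
#'   and `log`.
#' @export
run_pipeline <- function(config, signals) {
  if (!inherits(config, "run_config")) {
    stop("`config` must be a run_config", call. = FALSE)
  }
  for (ch in c("ch1", "ch2")) {
    if (!inherits(signals[[ch]], "signal_trace")) {
      stop(sprintf("`signals$%s` must be a signal_trace", ch), call. = FALSE)
    }
    if (abs(signals[[ch]]$fs - config$fs) > 1e-3 * config$fs) {
      stop(sprintf("%s sampling rate %g Hz does not match config fs %g Hz",
                   ch, signals[[ch]]$fs, config$fs), call. = FALSE)
    }
  }
  b <- design_bandpass(config$fir)
  f1 <- fir_filter(signals$ch1, b)
  f2 <- fir_filter(signals$ch2, b)
  ev1 <- detect_features(f1, window = config$window, gain = config$gain)
  ev2 <- detect_features(f2, window = config$window, gain = config$gain)
  pairs <- pair_beats(ev1, ev2, mode = config$mode, max_ptt = config$max_ptt,
                      fs = config$fs)
  if (nrow(pairs) < 3L) {
    stop(sprintf("only %d paired beats: need at least 3 for a reliable median",
                 nrow(pairs)), call. = FALSE)
  }
  pwv <- pwv_samples(pairs, fs = config$fs, L = config$L)
  med <- aggregate_pwv(pwv$pwv_mps)
  bp <- estimate_bp(med, config$artery, k = config$k, method = config$split)
  log <- list(
    fir = list(taps = length(b), fc1 = config$fir$fc1, fc2 = config$fir$fc2,
               beta = config$fir$beta, group_delay = attr(b, "group_delay")),
    detect = list(window = config$window, gain = config$gain,
                  events_ch1 = nrow(ev1), events_ch2 = nrow(ev2)),
    pairing = list(mode = config$mode, max_ptt = config$max_ptt,
                   paired = nrow(pairs),
                   unpaired_p1 = attr(pairs, "unpaired_p1"),
                   unpaired_p2 = attr(pairs, "unpaired_p2")),
    pwv = list(n = nrow(pwv), median_mps = med, L = config$L),
    bp = list(k = config$k, split = config$split)
  )
  structure(list(bp = bp, pwv = pwv, median_pwv = med,
                 events = list(ch1 = ev1, ch2 = ev2),
                 pairs = pairs, log = log),
            class = "bp_run")
}

#' @export
print.bp_run <- function(x, ...) {
  cat(sprintf("<bp_run> %d beats, median PWV %.2f m/s -> ", nrow(x$pwv),
              x$median_pwv))
  print(x$bp)
  invisible(x)
}

#' Simulate a noise-free validation study over a synthetic cohort
#'
#' For each subject: synthesize a dual-channel recording whose true transit
#' time is the subject's derived PTT, run the full pipeline, and tabulate
#' estimated vs. true pressures.  Noise, wander and jitter are off — the
#' residual estimation error is then dominated by the one-sample
#' quantization of the transit time.  Heart rates are drawn uniformly per
#' subject.
#'
#' @param cohort A [generate_cohort()] list.
#' @param duration Recording length per subject in seconds (default 30).
#' @param fs Sampling rate in Hz (default 10000).
#' @param hr_range Heart-rate range in bpm to draw from (default 60-90).
#' @param seed Integer seed for the heart-rate draws.
#' @param config_fn Optional function `(subject, hr)` returning the
#'   [run_config()] to use; defaults to the standard device configuration
#'   with the subject's artery.
#' @return A data.frame with one row per subject: true and estimated MAP /
#'   SBP / DBP, true and measured PTT (s), PWV, heart rate and beat count.
#' @export
run_cohort_study <- function(cohort, duration = 30, fs = 10000,
                             hr_range = c(60, 90), seed = NULL,
                             config_fn = NULL) {
  if (!inherits(cohort, "synthetic_cohort")) {
    stop("`cohort` must come from generate_cohort()", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  hrs <- runif(length(cohort), hr_range[1], hr_range[2])
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    cfg <- if (is.null(config_fn)) {
      run_config(fs = fs, artery = s$artery, L = s$L)
    } else {
      config_fn(s, hrs[i])
    }
    sim <- synth_config(
      heart_rate = hrs[i], duration = duration, fs = fs,
      ptt_true = s$derived_ptt,
      amplitude_jitter = 0,
      baseline_wander = list(amplitude = 0, freq = 0.3),
      noise_sd = 0
    )
    traces <- generate_dual_channel(sim)
    run <- run_pipeline(cfg, traces)
    rows[[i]] <- data.frame(
      subject = i,
      true_map = s$true_map, est_map = run$bp$map,
      true_sbp = s$true_sbp, est_sbp = run$bp$sbp,
      true_dbp = s$true_dbp, est_dbp = run$bp$dbp,
      ptt_true = s$derived_ptt,
      ptt_meas = median(run$pwv$ptt_s),
      pwv_true = s$derived_pwv, pwv_meas = run$median_pwv,
      heart_rate = hrs[i], n_beats = nrow(run$pwv)
    )
  }
  do.call(rbind, rows)
}
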