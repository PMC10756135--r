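test_that("dynamic gradient follows the RMS * CV * gain definition", {
  # hand computation: mean 1.5, RMS sqrt(4.5), sd 1.5, CV 100
  g <- dynamic_gradient(c(0, 0, 3, 3), gain = 1.1)
  expect_equal(g$mean, 1.5)
  expect_equal(g$rms, sqrt(4.5))
  expect_equal(g$sd, 1.5)
  expect_equal(g$cv, 100)
  expect_equal(g$gradient, sqrt(4.5) * 1.0 * 1.1)
  # flat window: zero dispersion, zero gradient
  expect_equal(dynamic_gradient(rep(2, 10))$gradient, 0)
  # zero mean magnitude treated as flat
  expect_equal(dynamic_gradient(rep(0, 5))$gradient, 0)
  # scaling the window scales the gradient linearly (CV invariant)
  w <- c(0.2, 1.4, 0.8, 2.4, 0.1)
  expect_equal(dynamic_gradient(3 * w)$gradient,
               3 * dynamic_gradient(w)$gradient, tolerance = 1e-12)
  expect_equal(dynamic_gradient(3 * w)$cv, dynamic_gradient(w)$cv,
               tolerance = 1e-12)
})

test_that("state machine hand-trace emits the stored extremum", {
  seqv <- c(0, 1, 2, 3, 2.9, 2.5, 1)
  st <- detector_init()
  events <- list()
  for (i in seq_along(seqv)) {
    r <- detector_step(st, i - 1L, seqv[i], gradient = 1)
    st <- r$state
    if (!is.null(r$event)) events[[length(events) + 1L]] <- r$event
  }
  expect_length(events, 1L)
  expect_identical(events[[1]]$kind, "peak")
  expect_identical(events[[1]]$value, 3)
  expect_identical(events[[1]]$index, 3L)  # where 3 was first seen
  # continuation: descending then rising emits the trough at its own index
  cont <- c(0.5, 1, 2)
  for (i in seq_along(cont)) {
    r <- detector_step(st, 6L + i, cont[i], gradient = 1)
    st <- r$state
    if (!is.null(r$event)) events[[length(events) + 1L]] <- r$event
  }
  expect_length(events, 2L)
  expect_identical(events[[2]]$kind, "trough")
  expect_identical(events[[2]]$value, 0.5)
  expect_identical(events[[2]]$index, 7L)
})

test_that("monotone signals and out-of-order indices are handled", {
  st <- detector_init()
  for (i in 0:20) {
    r <- detector_step(st, i, i / 5, gradient = 0.5)
    st <- r$state
    expect_null(r$event)
  }
  expect_error(detector_step(st, 3, 1, gradient = 0.5), "increasing")
})

test_that("a clean 30 s recording at 60 bpm yields 30 peaks with alternating feet", {
  tr <- generate_dual_channel(quiet_config())
  ev <- detect_features(fir_filter(tr$ch1, design_bandpass(fir_spec())))
  expect_identical(sum(ev$kind == "peak"), 30L)
  expect_identical(sum(ev$kind == "trough"), 29L)
  expect_true(all(ev$kind[seq(1, nrow(ev), by = 2)] == "peak"))
  expect_true(all(diff(ev$index) > 0))
})

test_that("detection indices are invariant to amplitude scaling", {
  tr <- generate_dual_channel(quiet_config(duration = 10))
  b <- design_bandpass(fir_spec())
  f <- fir_filter(tr$ch1, b)
  e1 <- detect_features(f)
  e2 <- detect_features(signal_trace(2 * f$x, f$fs))
  expect_identical(e1$kind, e2$kind)
  expect_identical(e1$index, e2$index)
  expect_equal(e2$value, 2 * e1$value, tolerance = 1e-12)
})

test_that("streaming detector equals the offline from-scratch oracle", {
  set.seed(101)
  for (rep in 1:100) {
    n <- 400
    kind <- rep %% 3
    x <- if (kind == 0) {
      cumsum(rnorm(n))                              # random walk
    } else if (kind == 1) {
      5 + sin(2 * pi * 3 * (1:n) / 100) + rnorm(n, sd = 0.3)  # noisy tone
    } else {
      abs(rnorm(n)) + 0.5                           # unipolar noise
    }
    got <- detect_features(signal_trace(x, fs = 100), window = 50)
    ora <- detect_oracle(x, M = 50)
    expect_identical(nrow(got), nrow(ora))
    if (nrow(got) > 0) {
      expect_identical(got$kind, ora$kind)
      expect_identical(got$index, as.integer(ora$index))
      expect_equal(got$value, ora$value, tolerance = 1e-12)
    }
  }
})

test_that("retained detector state is constant in trace length", {
  set.seed(5)
  s1 <- attr(detect_features(signal_trace(rnorm(500), 100), window = 50),
             "detector_state")
  s2 <- attr(detect_features(signal_trace(rnorm(50000), 100), window = 50),
             "detector_state")
  expect_identical(length(s1), length(s2))
  expect_identical(names(s1), names(s2))
})

test_that("event kinds strictly alternate on noisy recordings", {
  tr <- generate_dual_channel(synth_config(duration = 15, seed = 31))
  ev <- detect_features(fir_filter(tr$ch1, design_bandpass(fir_spec())))
  expect_gt(nrow(ev), 2)
  expect_true(all(ev$kind[-1] != ev$kind[-nrow(ev)]))
  expect_true(all(diff(ev$index) > 0))
})

test_that("adding a DC offset before the default filter leaves events in place", {
  tr <- generate_dual_channel(quiet_config(duration = 10))
  b <- design_bandpass(fir_spec())
  e0 <- detect_features(fir_filter(tr$ch1, b))
  shifted <- signal_trace(tr$ch1$x + 500, tr$ch1$fs)
  e1 <- detect_features(fir_filter(shifted, b))
  expect_identical(e0$kind, e1$kind)
  expect_identical(e0$index, e1$index)
})

test_that("halved window tracks alternating 50/100 bpm intervals without misses", {
  beat_times <- cumsum(c(0.2, rep(c(1.2, 0.6), 12)))
  cfg <- synth_config(duration = ceiling(max(beat_times)) + 1,
                      beat_times = beat_times, noise_sd = 0,
                      amplitude_jitter = 0,
                      baseline_wander = list(amplitude = 0, freq = 0.3))
  tr <- generate_dual_channel(cfg)
  ev <- detect_features(fir_filter(tr$ch1, design_bandpass(fir_spec())),
                        window = 5000)  # M = fs / 2
  expect_identical(sum(ev$kind == "peak"), length(tr$beat_times))
})

test_that("raising the gain reduces false positives on a low-SNR trace", {
  # peak SNR ~ 6 dB: noise sd at half the pulse amplitude, unfiltered
  cfg <- synth_config(duration = 20, noise_sd = 150, amplitude = c(300, 300),
                      amplitude_jitter = 0,
                      baseline_wander = list(amplitude = 0, freq = 0.3),
                      seed = 7)
  tr <- generate_dual_channel(cfg)
  n_hi <- nrow(detect_features(tr$ch1, gain = 1.1))
  n_lo <- nrow(detect_features(tr$ch1, gain = 1.0))
  expect_lte(n_hi, n_lo)
})
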