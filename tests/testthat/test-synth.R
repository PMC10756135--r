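test_that("config invariants are enforced", {
  expect_error(synth_config(heart_rate = 20), "36")
  expect_error(synth_config(heart_rate = 400), "36")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
  expect_error(synth_config(duration = 0), "duration")
  # a transit time at or beyond the beat interval makes pairing ambiguous
  expect_error(synth_config(heart_rate = 60, ptt_true = 1.0), "ambiguous")
  expect_error(synth_config(heart_rate = 120, ptt_true = 0.5), "ambiguous")
})

test_that("noise-free trace contains the expected number of beats", {
  cases <- list(c(60, 30, 30), c(100, 30, 50), c(72, 25, 30), c(40, 30, 20))
  for (cs in cases) {
    tr <- generate_dual_channel(quiet_config(heart_rate = cs[1],
                                             duration = cs[2]))
    expect_identical(length(tr$beat_times), as.integer(cs[3]))
    expect_identical(length(tr$ch1$x), as.integer(round(cs[2] * 1e4)))
    expect_identical(length(tr$ch2$x), length(tr$ch1$x))
  }
})

test_that("channel 2 is channel 1 delayed by round(ptt_true * fs) samples", {
  for (ptt_ms in c(2, 5, 10)) {
    tr <- generate_dual_channel(quiet_config(duration = 5,
                                             ptt_true = ptt_ms / 1e3))
    d <- tr$delay_samples
    expect_identical(d, as.integer(round(ptt_ms / 1e3 * 1e4)))
    n <- length(tr$ch1$x)
    expect_identical(tr$ch2$x[(d + 1):n], tr$ch1$x[1:(n - d)])
    expect_true(all(tr$ch2$x[seq_len(d)] == 0))
  }
})

test_that("cross-correlation lag between noise-free channels equals the true delay", {
  tr <- generate_dual_channel(quiet_config(duration = 5, ptt_true = 0.01))
  lags <- 0:300
  xc <- vapply(lags, function(l) {
    n <- length(tr$ch1$x)
    sum(tr$ch1$x[1:(n - l)] * tr$ch2$x[(l + 1):n])
  }, numeric(1))
  expect_identical(lags[which.max(xc)], 100L)
})

test_that("identical config and seed give bit-identical noisy traces", {
  cfg <- synth_config(duration = 3, seed = 11)
  a <- generate_dual_channel(cfg)
  b <- generate_dual_channel(cfg)
  expect_identical(a$ch1$x, b$ch1$x)
  expect_identical(a$ch2$x, b$ch2$x)
  c2 <- generate_dual_channel(synth_config(duration = 3, seed = 12))
  expect_false(identical(a$ch1$x, c2$ch1$x))
})

test_that("full detect+pair chain recovers the true transit time on clean signals", {
  tr <- generate_dual_channel(quiet_config(duration = 10, ptt_true = 0.005))
  b <- design_bandpass(fir_spec())
  ev1 <- detect_features(fir_filter(tr$ch1, b))
  ev2 <- detect_features(fir_filter(tr$ch2, b))
  pairs <- pair_beats(ev1, ev2, mode = "pp", fs = 1e4)
  expect_identical(nrow(pairs), length(tr$beat_times))
  ptt <- compute_ptt(pairs, fs = 1e4)
  # every beat pair, not just the aggregate, sits within one sample period
  expect_true(all(abs(ptt - 0.005) <= 1e-4 + 1e-12))
})

test_that("forward subject generation matches a numeric inversion oracle", {
  art <- artery_params(D = 2.5e-3, h = 0.3e-3)
  s <- generate_subject(90, art, L = 0.03)
  # independent route: root-find the pressure whose forward PWV matches
  root <- uniroot(function(p) mk_forward(p, art) - s$derived_pwv,
                  c(1, 400), tol = 1e-12)$root
  expect_equal(root, 90, tolerance = 1e-9)
  expect_equal(s$derived_ptt, 0.03 / s$derived_pwv, tolerance = 1e-12)
  expect_lt(s$true_dbp, s$true_map)
  expect_gt(s$true_sbp, s$true_map)
})

test_that("derived PWV increases strictly with true MAP", {
  art <- artery_params()
  s80 <- generate_subject(80, art)
  s120 <- generate_subject(120, art)
  expect_gt(s120$derived_pwv, s80$derived_pwv)
  expect_lt(s120$derived_ptt, s80$derived_ptt)
})

test_that("derived PTT over 3 cm at 6 m/s is 5 ms", {
  expect_equal(0.03 / 6, 0.005)
  art <- artery_params()
  p <- mk_inverse(6, art)
  s <- generate_subject(p, art, L = 0.03)
  expect_equal(s$derived_ptt, 0.005, tolerance = 1e-12)
})

test_that("cohort generation is seeded, validated and physiologically bounded", {
  a <- generate_cohort(32, seed = 5)
  b <- generate_cohort(32, seed = 5)
  expect_identical(a, b)
  expect_error(generate_cohort(0), "n")
  expect_error(generate_cohort(4, ranges = list(D = c(3e-3, 2e-3),
                                                h = c(2e-4, 4e-4),
                                                map = c(70, 110))),
               "ordered")
  big <- generate_cohort(100, seed = 9)
  ptt <- vapply(big, function(s) s$derived_ptt, numeric(1))
  # transit times must fit inside a beat even at the slowest valid rate
  expect_true(all(ptt > 0 & ptt < 60 / 36))
  for (s in big) {
    expect_lt(s$artery$h, s$artery$D)
    expect_true(s$true_dbp < s$true_map && s$true_map < s$true_sbp)
  }
})
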