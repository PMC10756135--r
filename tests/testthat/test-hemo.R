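test_that("artery parameter invariants are enforced", {
  expect_error(artery_params(D = 2.5e-3, h = 3e-3), "smaller")
  expect_error(artery_params(D = -1e-3), "positive")
  expect_error(artery_params(xi = 0), "positive")
})

test_that("forward map agrees with a bisection oracle and scaling laws", {
  art <- artery_params(D = 2.5e-3, h = 0.3e-3)
  pwv90 <- mk_forward(90, art)
  # independent route: bisect the forward map to recover the pressure
  lo <- 1; hi <- 400
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (mk_forward(mid, art) < pwv90) lo <- mid else hi <- mid
  }
  expect_equal((lo + hi) / 2, 90, tolerance = 1e-9)
  # doubling wall thickness multiplies PWV by sqrt(2)
  art2h <- artery_params(D = 2.5e-3, h = 0.6e-3)
  expect_equal(mk_forward(90, art2h), sqrt(2) * pwv90, tolerance = 1e-12)
  # monotone in pressure, decreasing in diameter
  expect_true(all(diff(mk_forward(seq(40, 200, by = 5), art)) > 0))
  artD <- artery_params(D = 3e-3, h = 0.3e-3)
  expect_lt(mk_forward(90, artD), pwv90)
  expect_error(mk_forward(-10, art), "positive")
})

test_that("forward/inverse round trip holds to 1e-9 over the pressure range", {
  for (D in c(2.0e-3, 2.5e-3, 3.0e-3)) {
    for (h in c(0.2e-3, 0.3e-3, 0.4e-3)) {
      art <- artery_params(D = D, h = h)
      p <- seq(40, 200, by = 10)
      expect_equal(mk_inverse(mk_forward(p, art), art), p,
                   tolerance = 1e-9)
      # wave speeds this geometry can actually produce in the valid range
      pwv <- mk_forward(c(41, 90, 140, 199), art)
      expect_equal(mk_forward(mk_inverse(pwv, art), art), pwv,
                   tolerance = 1e-9)
    }
  }
  expect_error(mk_inverse(1e-9, artery_params()), "non-physical")
})

test_that("inverse sensitivity matches the analytic derivative 2/(xi PWV)", {
  art <- artery_params()
  for (pwv in c(4, 6, 12)) {
    fd <- (mk_inverse(pwv * 1.0001, art) - mk_inverse(pwv * 0.9999, art)) /
      (0.0002 * pwv)
    expect_equal(fd, 2 / (art$xi * pwv), tolerance = 1e-6)
  }
  # a +1 % PWV error at 6 m/s shifts MAP by ~0.645 mmHg
  shift <- mk_inverse(6 * 1.01, art) - mk_inverse(6, art)
  expect_equal(shift, 2 / art$xi * log(1.01), tolerance = 1e-12)
  expect_equal(shift, 0.645, tolerance = 0.01)
  # at fixed PWV a larger lumen implies a higher pressure
  expect_gt(mk_inverse(6, artery_params(D = 3e-3, h = 0.3e-3)),
            mk_inverse(6, artery_params(D = 2.5e-3, h = 0.3e-3)))
})

test_that("mmHg/Pa conversion order does not change the inverse", {
  art <- artery_params()
  pwv <- seq(4, 25, by = 1.5)
  # route A: compare moduli on the Pa scale
  einc_pa <- pwv^2 * art$rho_blood * art$D / art$h
  route_a <- log(einc_pa / (art$E0 * 133.322)) / art$xi
  # route B: convert the modulus to mmHg first
  einc_mmhg <- einc_pa / 133.322
  route_b <- log(einc_mmhg / art$E0) / art$xi
  expect_equal(route_a, route_b, tolerance = 1e-9)
  expect_equal(mk_inverse(pwv, art), route_a, tolerance = 1e-9)
})

test_that("cuff MAP approximation follows the 1/3-2/3 weighting", {
  expect_equal(map_from_cuff(120, 80), 93 + 1 / 3)
  expect_equal(map_from_cuff(150, 90), 110)
  expect_equal(map_from_cuff(95, 95), 95)  # degenerate equality
  expect_error(map_from_cuff(80, 120), "sbp >= dbp")
})

test_that("MAP split follows the device convention and flags its inconsistency", {
  s <- split_map(100, k = 0.76)
  expect_equal(s$dbp, 76)
  expect_equal(s$sbp, 118.24)
  # ordering holds across the clinical range for any valid k
  for (k in c(0.3, 0.5, 0.76, 0.95)) {
    for (map in c(60, 90, 130)) {
      sp <- split_map(map, k = k)
      expect_lt(sp$dbp, map)
      expect_gt(sp$sbp, map)
    }
  }
  # the algebraically consistent inversion differs from the printed pair
  cons <- split_map(100, k = 0.76, method = "consistent")
  expect_equal(cons$sbp, 3 * 100 - 2 * 76)
  expect_false(isTRUE(all.equal(cons$sbp, s$sbp)))
  # only the consistent branch reproduces MAP through the cuff formula
  expect_equal(map_from_cuff(cons$sbp, cons$dbp), 100)
  expect_false(isTRUE(all.equal(map_from_cuff(s$sbp, s$dbp), 100)))
  expect_error(split_map(100, k = 1.2), "0, 1")
  expect_error(split_map(-5), "positive")
})

test_that("estimate_bp composes inversion and split with provenance", {
  art <- artery_params()
  bp <- estimate_bp(10, art)
  expect_s3_class(bp, "bp_estimate")
  expect_equal(bp$map, mk_inverse(10, art))
  expect_equal(bp$dbp, bp$map * 0.76)
  expect_true(bp$dbp < bp$map && bp$map < bp$sbp)
  expect_match(bp$provenance$map, "Moens-Korteweg")
  # monotone in PWV
  bps <- vapply(c(6, 8, 10, 14), function(v) estimate_bp(v, art)$map,
                numeric(1))
  expect_true(all(diff(bps) > 0))
})

test_that("single-subject recovery stays inside the quantization bound", {
  art <- artery_params(D = 2.6e-3, h = 0.32e-3)
  subj <- generate_subject(95, art, L = 0.03)
  tr <- generate_dual_channel(quiet_config(duration = 10,
                                           ptt_true = subj$derived_ptt))
  run <- run_pipeline(run_config(artery = art), tr)
  bound <- (2 / art$xi) * (1 / 1e4) / subj$derived_ptt
  expect_lt(abs(run$bp$map - 95), bound)
})
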