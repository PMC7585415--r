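# Peak finding, bi-exponential fitting, tau_w, extent of desensitization.

test_that("tau_w formula reproduces the printed worked examples", {
  # wild type: 4.8 s and 24.4 s with a ~1/3 fast share give ~18 s
  expect_equal(tau_weighted(4.8, 24.4, 33.3), 17.87, tolerance = 1e-3)
  expect_lt(abs(tau_weighted(4.8, 24.4, 33.3) - 18), 0.5)
  # SU3 single mutant: 2.7 s / 7.1 s at 20% give the printed 6.2 s
  expect_equal(round(tau_weighted(2.7, 7.1, 20.0), 1), 6.2)
})

test_that("peak location, rise-time diagnostic and no-peak flagging", {
  tr <- toy_biexp_trace()
  pk <- find_peak(tr)
  expect_equal(pk$time, 0, tolerance = 0.002)
  expect_equal(pk$magnitude, 2, tolerance = 1e-6)
  flat <- gabadesens:::new_current_trace(seq(0, 1, 0.002),
                                         rep(0, 501))
  expect_true(find_peak(flat)$no_peak)
  # synthetic recording with the default exchange: 20-80% rise in 20-25 ms
  cfg <- recording_config(seed = 5)
  tro <- generate_trace(list(tau_fast = 4.8, tau_slow = 24.4,
                             pct_A_fast = 33.3, pct_I_res = 10), cfg)
  rise <- find_peak(tro)$rise_20_80
  expect_gte(rise, 0.020)
  expect_lte(rise, 0.025)
})

test_that("noiseless bi-exponential round-trip recovers parameters to 0.5%", {
  tr <- toy_biexp_trace(tau_f = 4.8, tau_s = 24.4, a = 1/3, plateau = 0.1,
                        t_app = 60)
  obs <- fit_biexponential(tr)
  expect_equal(obs$tau_fast, 4.8, tolerance = 0.005)
  expect_equal(obs$tau_slow, 24.4, tolerance = 0.005)
  expect_equal(obs$pct_A_fast, 100 / 3, tolerance = 0.005)
  expect_false(obs$collapsed)
  expect_gt(obs$tau_w, obs$tau_fast)
  expect_lt(obs$tau_w, obs$tau_slow)
})

test_that("pure mono-exponential input collapses with pct_A_fast = 100", {
  times <- seq(0, 30, 0.002)
  tr <- gabadesens:::new_current_trace(times,
                                       -2 * (0.05 + 0.95 * exp(-times / 3)),
                                       application = c(0, 30))
  obs <- fit_biexponential(tr)
  expect_true(obs$collapsed)
  expect_equal(obs$pct_A_fast, 100)
  expect_equal(obs$tau_fast, 3, tolerance = 0.01)
  expect_true(is.na(obs$tau_slow))
})

test_that("fit is invariant to current scaling and sign convention", {
  tr <- toy_biexp_trace(tau_f = 2, tau_s = 15, a = 0.6, plateau = 0.05)
  o1 <- fit_biexponential(tr)
  tr2 <- tr; tr2$current <- -500 * tr2$current  # outward, rescaled
  o2 <- fit_biexponential(tr2)
  expect_equal(o1$tau_fast, o2$tau_fast, tolerance = 1e-8)
  expect_equal(o1$tau_slow, o2$tau_slow, tolerance = 1e-8)
  expect_equal(o1$pct_A_fast, o2$pct_A_fast, tolerance = 1e-8)
})

test_that("desensitization extent handles the trivial and printed cases", {
  times <- seq(0, 10, 0.002)
  flat <- gabadesens:::new_current_trace(times, rep(-1, length(times)),
                                         application = c(0, 10))
  expect_equal(desensitization_extent(flat), 0)
  gone <- gabadesens:::new_current_trace(times, -exp(-times / 0.2),
                                         application = c(0, 10))
  expect_equal(desensitization_extent(gone), 1, tolerance = 1e-3)
  zero <- gabadesens:::new_current_trace(times, rep(0, length(times)))
  expect_error(desensitization_extent(zero), "undefined")
  # wild-type-like trace with a 10% measured residual
  cfg <- recording_config(seed = 9)
  tr <- generate_trace(list(tau_fast = 4.8, tau_slow = 24.4,
                            pct_A_fast = 33.3, pct_I_res = 10), cfg)
  expect_equal(desensitization_extent(tr), 0.90, tolerance = 0.015)
})

test_that("tau_w from fitted components lies between tau_fast and tau_slow
           over random parameter draws", {
  set.seed(101)
  for (i in 1:20) {
    tf <- stats::runif(1, 0.1, 5)
    ts <- tf * stats::runif(1, 3, 20)
    a <- stats::runif(1, 0.15, 0.9)
    tr <- toy_biexp_trace(tau_f = tf, tau_s = ts, a = a,
                          plateau = stats::runif(1, 0, 0.2),
                          t_app = max(6 * ts, 10))
    obs <- fit_biexponential(tr)
    if (!obs$collapsed) {
      expect_gte(obs$tau_w, obs$tau_fast)
      expect_lte(obs$tau_w, obs$tau_slow)
    }
  }
})
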