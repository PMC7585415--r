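# Synthetic TEVC trace generator.

test_that("trace generation is bit-reproducible for a fixed seed", {
  fit <- wt_fit("III", gamma = 100, epsilon = 10)
  gt <- list(variant = "III", params = fit$params)
  a <- generate_trace(gt, recording_config(seed = 7), t_app = 10)
  b <- generate_trace(gt, recording_config(seed = 7), t_app = 10)
  expect_identical(a$current, b$current)
  c <- generate_trace(gt, recording_config(seed = 8), t_app = 10)
  expect_false(identical(a$current, c$current))
})

test_that("noise-free unfiltered observable mode equals the analytic
           bi-exponential at the sample points", {
  cfg <- recording_config(exchange_tau = 0, filter_cutoff = NULL,
                          gaussian_noise_sd = 0)
  gt <- list(tau_fast = 2, tau_slow = 12, pct_A_fast = 40, pct_I_res = 0)
  tr <- generate_trace(gt, cfg, t_app = 30, t_pre = 0, noise = FALSE)
  t <- tr$time
  scale <- cfg$n_channels * cfg$unitary_current
  ana <- -scale * (0.4 * exp(-t / 2) + 0.6 * exp(-t / 12))
  expect_lt(max(abs(tr$current - ana)), 1e-9 * scale)
})

test_that("requested residual is the measured end-of-application residual", {
  cfg <- recording_config(seed = 2)
  tr <- generate_trace(list(tau_fast = 4.8, tau_slow = 24.4,
                            pct_A_fast = 33.3, pct_I_res = 10), cfg)
  obs <- fit_biexponential(tr)
  expect_equal(obs$pct_I_res, 10, tolerance = 0.05)
})

test_that("wild-type observables survive the full noise chain within
           5%/10%", {
  cfg <- recording_config(seed = 4)
  tr <- generate_trace(list(tau_fast = 4.8, tau_slow = 24.4,
                            pct_A_fast = 33.3, pct_I_res = 10), cfg)
  obs <- fit_biexponential(tr)
  expect_equal(obs$tau_fast, 4.8, tolerance = 0.05)
  expect_equal(obs$tau_slow, 24.4, tolerance = 0.10)
})

test_that("ground truth violating tau_fast <= tau_slow errors", {
  expect_error(generate_trace(list(tau_fast = 5, tau_slow = 1,
                                   pct_A_fast = 50, pct_I_res = 5),
                              recording_config()),
               "tau_fast <= tau_slow")
})

test_that("quadrupling the channel count halves the relative binomial
           noise at the plateau", {
  fit <- wt_fit("III", gamma = 100, epsilon = 10)
  gt <- list(variant = "III", params = fit$params)
  rel_sd <- function(nch) {
    cfg <- recording_config(n_channels = nch, gaussian_noise_sd = 0,
                            seed = 31)
    noisy <- generate_trace(gt, cfg, t_app = 20)
    det <- generate_trace(gt, cfg, t_app = 20, noise = FALSE)
    filt <- gabadesens:::lowpass_causal(-det$current, cfg$sample_rate,
                                        cfg$filter_cutoff)
    i <- noisy$time > 10
    stats::sd((noisy$current - (-filt))[i]) /
      (nch * cfg$unitary_current)
  }
  ratio <- rel_sd(5000) / rel_sd(20000)
  expect_equal(ratio, 2, tolerance = 0.25)
})
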