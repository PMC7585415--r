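# Ballpark inversions, wild-type calibration, multiplier fits, predictions.

test_that("Model I ballpark inversion matches the printed ballparks", {
  t <- wt_targets()
  bp <- ballpark_init_model_I(t)
  # A_fast/I_peak ~ 2D with a ~1/3 fast share
  expect_equal(bp$D, 0.333 / 2, tolerance = 0.01)
  expect_lt(abs(bp$D - 0.2), 0.05)
  # resulting rates within a factor 2 of the printed ~0.2 and ~1 per second
  expect_lt(max(bp$params$delta_plus / 0.2, 0.2 / bp$params$delta_plus), 2)
  expect_lt(max(bp$params$delta_minus / 1, 1 / bp$params$delta_minus), 2)
  # degenerate zero-amplitude case
  t0 <- observable_targets("X", 1, 10, pct_A_fast = 0)
  expect_equal(ballpark_init_model_I(t0)$D, 0)
})

test_that("Model II ballpark solves the quadratic amplitude relation", {
  # oracle: direct positive root of D^2 = f (1 + 2 D)
  quad_root <- function(f) {
    r <- polyroot(c(-f, -2 * f, 1))
    max(Re(r[abs(Im(r)) < 1e-9]))
  }
  t30 <- observable_targets("X", 4.8, 24.4, pct_A_fast = 30)
  bp30 <- ballpark_init_model_II(t30)
  expect_equal(bp30$D, quad_root(0.30), tolerance = 1e-9)
  expect_equal(bp30$D, (0.6 + sqrt(0.36 + 1.2)) / 2, tolerance = 1e-9)
  # printed outcome: D ~ 0.9 and delta+ ~ 0.14/s from tau_fast = 4.8 s
  expect_lt(abs(bp30$D - 0.9), 0.15)
  expect_equal(bp30$params$delta_plus, 0.14, tolerance = 0.3)
  t0 <- observable_targets("X", 1, 10, pct_A_fast = 1e-9)
  expect_lt(ballpark_init_model_II(t0)$D, 1e-4)
})

test_that("wild-type calibration is self-consistent: parameters used to
           generate targets are recovered", {
  truths <- list(
    III = rate_parameters(delta_plus = 0.3, delta_minus = 1.1,
                          delta3_plus = 0.0012, delta3_minus = 0.005,
                          gamma_coupling = 100, epsilon_coupling = 10),
    I = rate_parameters(delta_plus = 0.04, delta_minus = 0.15,
                        delta3_plus = 0.035, delta3_minus = 0.003))
  for (v in names(truths)) {
    truth <- truths[[v]]
    obs <- simulate_observables(v, truth)
    tg <- observable_targets("CWT", obs$tau_fast, obs$tau_slow,
                             obs$pct_A_fast, obs$pct_I_res)
    fit <- calibrate_wt(v, tg, gamma = truth$gamma_coupling,
                        epsilon = truth$epsilon_coupling)
    for (pn in c("delta_plus", "delta_minus", "delta3_plus",
                 "delta3_minus")) {
      expect_equal(fit$params[[pn]], truth[[pn]], tolerance = 0.02,
                   label = paste(v, pn))
    }
  }
})

test_that("Model I wild-type calibration reaches the printed observables
           with near-zero loss (four constraints, four parameters)", {
  fit <- wt_fit("I")
  expect_lt(fit$loss, 1e-6)
  expect_false(fit$flagged_nonfit)
  expect_equal(fit$observables$tau_fast, 4.8, tolerance = 0.01)
  expect_equal(fit$observables$tau_slow, 24.4, tolerance = 0.01)
})

test_that("Model III with gamma = 100, epsilon = 10 reproduces all four
           wild-type observables within 20%", {
  fit <- wt_fit("III", gamma = 100, epsilon = 10)
  o <- fit$observables
  expect_equal(o$tau_fast, 4.8, tolerance = 0.2)
  expect_equal(o$tau_slow, 24.4, tolerance = 0.2)
  expect_equal(o$pct_A_fast, 33.3, tolerance = 0.2)
  expect_equal(o$pct_I_res, 10, tolerance = 0.2)
})

test_that("unit multipliers predict wild-type observables", {
  fit <- wt_fit("I")
  wtp <- predict_construct("I", fit$params, mutation_profile())
  expect_equal(wtp$tau_fast, fit$observables$tau_fast, tolerance = 1e-6)
  expect_equal(wtp$pct_I_res, fit$observables$pct_I_res, tolerance = 1e-6)
})

test_that("Model II-beta restores a two-component C3 decay where plain
           Model II collapses it to a mono-exponential", {
  wfII <- workflow("II")
  c3_II <- wfII$predictions[wfII$predictions$construct == "C3", ]
  expect_equal(c3_II$pct_A_fast, 100, tolerance = 1e-6)
  wfIIb <- workflow("II_BETA")
  c3_IIb <- wfIIb$predictions[wfIIb$predictions$construct == "C3", ]
  expect_lt(c3_IIb$pct_A_fast, 99)
  expect_false(is.na(c3_IIb$tau_slow))
  expect_gt(c3_IIb$tau_slow / c3_IIb$tau_fast, 1.5)
})

test_that("objective is invariant to the order of mutant targets", {
  tb <- printed_observables()
  wf1 <- fit_mutation_ratios("I", wt_fit("I"),
                             targets_from_table(tb, c("C4", "C5")))
  wf2 <- fit_mutation_ratios("I", wt_fit("I"),
                             targets_from_table(tb, c("C5", "C4")))
  expect_equal(wf1$multipliers, wf2$multipliers, tolerance = 1e-8)
})

test_that("model comparison report joins fixtures and computes fold errors", {
  preds <- data.frame(variant = "X", construct = c("CWT", "C4", "C45"),
                      tau_fast = c(4.8, 2.9, 0.18),
                      tau_slow = c(24.4, 7.3, NA),
                      pct_A_fast = c(33.3, 86.7, 98.8),
                      pct_I_res = c(10, NA, 0.8),
                      tau_w = c(18, 3.4, NA))
  rep <- model_comparison_report(preds)
  expect_equal(rep$fold_error_tau_fast, rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(attr(rep, "flags")["X"]), "synergistic")
})
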