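# Master-equation propagation and current conversion.

test_that("3-state activation reaches the closed-form steady state", {
  p <- rate_parameters()
  sch <- build_scheme("I", p, desensitizable = character())
  traj <- propagate(sch, agonist_protocol(durations = 5, dt = 0.002))
  A <- 0.01
  expected <- p$k_on * A * p$beta /
    (p$k_on * A * p$beta + p$k_on * A * p$alpha + p$k_off * p$alpha)
  expect_equal(traj$probabilities[nrow(traj$probabilities), "AO"],
               expected, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("two-state relaxation time constant is 1/(delta+ + delta-)", {
  # open <-> desensitized toy captured with a single desensitizable subunit
  # and saturating instant activation
  p <- rate_parameters(k_on = 1e9, beta = 5e4, alpha = 1e-3,
                       delta_plus = 0.8, delta_minus = 0.4,
                       delta3_plus = 0.8, delta3_minus = 0.4)
  sch <- build_scheme("I", p, desensitizable = "SU4")
  traj <- propagate(sch, agonist_protocol(durations = 20, dt = 0.002))
  occ <- traj$probabilities[, "AO"]
  t <- traj$times
  sel <- t >= 0.5 & t <= 12
  p_inf <- occ[length(occ)]
  lam <- -stats::coef(stats::lm(log(occ[sel] - p_inf + 1e-15) ~ t[sel]))[[2]]
  expect_equal(lam, p$delta_plus + p$delta_minus, tolerance = 0.01)
})

test_that("without desensitization the open occupancy never decays", {
  p <- rate_parameters(delta_plus = 1e-12, delta_minus = 1,
                       delta3_plus = 1e-12, delta3_minus = 1)
  sch <- build_scheme("I", p)
  traj <- propagate(sch, agonist_protocol(durations = 10, dt = 0.002))
  occ <- traj$probabilities[, "AO"]
  peak <- which.max(occ)
  expect_true(all(diff(occ[peak:length(occ)]) > -1e-9))
})

test_that("probability is conserved over 60 s at dt = 2 ms", {
  p <- rate_parameters(gamma_coupling = 100, epsilon_coupling = 10)
  sch <- build_scheme("III", p)
  traj <- propagate(sch, agonist_protocol(durations = 60, dt = 0.002))
  expect_lt(max(abs(rowSums(traj$probabilities) - 1)), 1e-8)
  expect_true(all(traj$probabilities >= -1e-12))
  expect_true(all(traj$probabilities <= 1 + 1e-12))
})

test_that("expm stepping matches a stiff adaptive integrator", {
  skip_if_not_installed("deSolve")
  p <- rate_parameters(gamma_coupling = 100, epsilon_coupling = 10)
  sch <- build_scheme("III", p)
  traj <- propagate(sch, agonist_protocol(durations = 30, dt = 0.01))
  A <- t(sch$generator)
  deriv <- function(t, y, parms) list(as.numeric(A %*% y))
  y0 <- c(1, rep(0, 9))
  sol <- deSolve::lsoda(y0, traj$times, deriv, NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(sol[, -1] - traj$probabilities)), 1e-6)
})

test_that("halving dt leaves final occupancies unchanged (expm exactness)", {
  p <- rate_parameters()
  sch <- build_scheme("II", p)
  t1 <- propagate(sch, agonist_protocol(durations = 10, dt = 0.002))
  t2 <- propagate(sch, agonist_protocol(durations = 10, dt = 0.001))
  expect_lt(max(abs(t1$probabilities[nrow(t1$probabilities), ] -
                      t2$probabilities[nrow(t2$probabilities), ])), 1e-8)
})

test_that("eigen fast path agrees with expm stepping", {
  p <- rate_parameters(gamma_coupling = 100, epsilon_coupling = 10)
  sch <- build_scheme("III", p)
  traj <- propagate(sch, agonist_protocol(durations = 5, dt = 0.01))
  P <- gabadesens:::propagate_times(sch, traj$times)
  expect_lt(max(abs(P - traj$probabilities)), 1e-9)
})

test_that("current is conducting occupancy times N times i, inward negative", {
  p <- rate_parameters()
  schI <- build_scheme("I", p)
  schII <- build_scheme("II", p)
  traj <- propagate(schI, agonist_protocol(durations = 20, dt = 0.002))
  trI <- current_from_occupancy(traj, schI, n_channels = 1000,
                                unitary_current = 2)
  expect_true(all(trI$current <= 0))
  # conducting-set inclusion: Model II current magnitude dominates Model I
  trII <- current_from_occupancy(traj, schII, n_channels = 1000,
                                 unitary_current = 2)
  expect_true(all(abs(trII$current) - abs(trI$current) >= -1e-12))
  # zero channels give an identically zero trace
  tr0 <- current_from_occupancy(traj, schI, n_channels = 0)
  expect_true(all(tr0$current == 0))
  # occupancy all in R gives zero current
  sch0 <- build_scheme("I", p, agonist_conc = 0)
  traj0 <- propagate(sch0, agonist_protocol(durations = 1,
                                            concentrations = 0))
  tr00 <- current_from_occupancy(traj0, sch0)
  expect_true(all(tr00$current == 0))
})

test_that("binomial channel noise is unbiased, seeded, and degenerate at
           p = 0", {
  p <- rate_parameters()
  sch <- build_scheme("II", p)
  traj <- propagate(sch, agonist_protocol(durations = 2, dt = 0.01))
  det <- current_from_occupancy(traj, sch, n_channels = 20000,
                                unitary_current = 1)
  pk_det <- max(abs(det$current))
  peaks <- vapply(1:100, function(s) {
    max(abs(sample_channel_noise(traj, sch, 20000, seed = s,
                                 unitary_current = 1)$current))
  }, numeric(1))
  # noisy peak slightly exceeds the deterministic peak (max of noise), but
  # its mean stays within a few SE of it
  se <- stats::sd(peaks) / 10
  expect_lt(abs(mean(peaks) - pk_det), max(3 * se, 3 * sqrt(pk_det)))
  a <- sample_channel_noise(traj, sch, 20000, seed = 42)
  b <- sample_channel_noise(traj, sch, 20000, seed = 42)
  expect_identical(a$current, b$current)
  sch0 <- build_scheme("I", p, agonist_conc = 0)
  traj0 <- propagate(sch0, agonist_protocol(durations = 1,
                                            concentrations = 0))
  z <- sample_channel_noise(traj0, sch0, 20000, seed = 1)
  expect_true(all(z$current == 0))
})

test_that("solution exchange slows the rise and warns when dt is coarse", {
  p <- rate_parameters()
  sch <- build_scheme("I", p, desensitizable = character())
  prot_fast <- agonist_protocol(durations = c(0.2, 2),
                                concentrations = c(0, 0.01), dt = 0.002)
  prot_slow <- agonist_protocol(durations = c(0.2, 2),
                                concentrations = c(0, 0.01), dt = 0.002,
                                exchange_tau = 0.05)
  expect_warning(traj_slow <- propagate(sch, prot_slow),
                 class = "gabadesens_dt_warning")
  traj_fast <- propagate(sch, prot_fast)
  i50 <- function(tr) tr$times[min(which(tr$probabilities[, "AO"] >
                                           0.5 * max(tr$probabilities[, "AO"])))]
  expect_gt(i50(traj_slow), i50(traj_fast))
})
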