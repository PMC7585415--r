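# Shared fixtures. Expensive calibrations are computed lazily and memoized
# so that every test file can reuse them within one run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

wt_targets <- function() targets_from_table()$CWT

wt_fit <- function(variant, gamma = 1, epsilon = 1) {
  memo(paste("wt", variant, gamma, epsilon, sep = "_"),
       calibrate_wt(variant, wt_targets(), gamma = gamma, epsilon = epsilon))
}

workflow <- function(variant, gamma = 1, epsilon = 1, sim = "a") {
  memo(paste("wf", variant, gamma, epsilon, sim, sep = "_"),
       run_model_workflow(variant, gamma = gamma, epsilon = epsilon,
                          sim = sim))
}

# a small synthetic biexponential trace with known components
toy_biexp_trace <- function(tau_f = 1, tau_s = 8, a = 0.4, plateau = 0.1,
                            t_app = 30, dt = 0.002, peak = 2) {
  times <- seq(0, t_app, by = dt)
  decay <- plateau + (1 - plateau) *
    (a * exp(-times / tau_f) + (1 - a) * exp(-times / tau_s))
  gabadesens:::new_current_trace(times, -peak * decay,
                                 application = c(0, t_app))
}
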