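# Synthetic TEVC-like recordings with known ground truth.

#' Recording configuration for synthetic traces
#'
#' Defaults emulate the acquisition conditions of the oocyte recordings the
#' package's synthetic traces stand in for: 500 Hz digitization, 100 Hz
#' low-pass filtering, a solution exchange giving a 20--80% current rise of
#' ~22 ms (single-exponential exchange, `ln(4) * exchange_tau`), and
#' 10,000--30,000 channels per cell (default 20,000). Gaussian instrument
#' noise defaults to 0.5% of the peak current.
#'
#' @param sample_rate Sampling rate, Hz (must exceed twice the filter
#'   cutoff).
#' @param filter_cutoff Low-pass cutoff, Hz; `NULL` disables filtering.
#' @param exchange_tau Solution-exchange time constant, seconds (0 = ideal
#'   step).
#' @param n_channels Channel count.
#' @param unitary_current Single-channel current magnitude (current units).
#' @param gaussian_noise_sd Instrument noise SD in current units; `NULL` =
#'   0.5% of the deterministic peak.
#' @param seed Integer seed for the noise draws.
#' @return An object of class `recording_config`.
#' @export
recording_config <- function(sample_rate = 500, filter_cutoff = 100,
                             exchange_tau = 0.016, n_channels = 20000,
                             unitary_current = 1e-4,
                             gaussian_noise_sd = NULL, seed = 1) {
  if (!is.null(filter_cutoff) && sample_rate <= 2 * filter_cutoff) {
    stop("sample_rate must exceed twice the filter cutoff", call. = FALSE)
  }
  stopifnot(exchange_tau >= 0, n_channels >= 0, unitary_current >= 0)
  cfg <- list(sample_rate = sample_rate, filter_cutoff = filter_cutoff,
              exchange_tau = exchange_tau, n_channels = n_channels,
              unitary_current = unitary_current,
              gaussian_noise_sd = gaussian_noise_sd, seed = seed)
  class(cfg) <- "recording_config"
  cfg
}

# 4-pole Butterworth low-pass, applied forward only (causal, like the
# acquisition hardware's analog filter).
lowpass_causal <- function(x, sample_rate, cutoff) {
  if (is.null(cutoff) || !is.finite(cutoff)) return(x)
  bf <- signal::butter(4, cutoff / (sample_rate / 2), type = "low")
  as.numeric(signal::filter(bf, x))
}

#' Generate a synthetic TEVC-like current trace
#'
#' Produces a realistic desensitizing current with known ground truth, in one
#' of two modes. Mechanism mode (`ground_truth` carries `variant`, `params`
#' and optionally `profile`): the master equation is propagated with the
#' config's exponential solution exchange and the conducting occupancy drives
#' the noise chain. Observable mode (`ground_truth` carries `tau_fast`,
#' `tau_slow`, `pct_A_fast`, `pct_I_res`): the bi-exponential decay is built
#' directly and multiplied by the exchange rise envelope. In both modes the
#' noise chain is binomial channel-count noise, additive Gaussian instrument
#' noise, causal low-pass filtering, and sampling at the configured rate.
#' The generating truth is stored in the trace's `"ground_truth"` attribute.
#'
#' @param ground_truth Named list, see Details above.
#' @param config A [recording_config()].
#' @param t_app Application duration, seconds.
#' @param t_pre Agonist-free baseline before the application, seconds.
#' @param noise Logical; `FALSE` gives the deterministic (noise-free,
#'   unfiltered when `config$filter_cutoff` is NULL) trace.
#' @return A `current_trace` with attributes `ground_truth`, `config`.
#' @export
generate_trace <- function(ground_truth, config = recording_config(),
                           t_app = 60, t_pre = 0.2, noise = TRUE) {
  dt <- 1 / config$sample_rate
  mechanism <- !is.null(ground_truth$variant)
  if (mechanism) {
    profile <- if (is.null(ground_truth$profile)) mutation_profile() else
      ground_truth$profile
    scheme <- build_scheme(ground_truth$variant, ground_truth$params,
                           profile)
    protocol <- agonist_protocol(
      durations = c(t_pre, t_app),
      concentrations = c(0, if (is.null(ground_truth$agonist_conc)) 0.01
                         else ground_truth$agonist_conc),
      dt = dt, exchange_tau = config$exchange_tau)
    traj <- withCallingHandlers(
      propagate(scheme, protocol),
      gabadesens_dt_warning = function(w) invokeRestart("muffleWarning"))
    p_cond <- rowSums(traj$probabilities[, scheme$conducting,
                                         drop = FALSE])
    times <- traj$times
    application <- application_window(protocol)
  } else {
    gt <- ground_truth
    stopifnot(!is.null(gt$tau_fast))
    tau_slow <- if (is.null(gt$tau_slow) || is.na(gt$tau_slow))
      gt$tau_fast else gt$tau_slow
    if (gt$tau_fast > tau_slow) {
      stop("ground truth violates tau_fast <= tau_slow", call. = FALSE)
    }
    a <- gt$pct_A_fast / 100
    r <- if (is.null(gt$pct_I_res) || is.na(gt$pct_I_res)) 0 else
      gt$pct_I_res / 100
    # r is the MEASURED residual after t_app; solve for the plateau C so
    # that C + (1-C) * (undecayed exponential tail at t_app) equals r
    s_end <- a * exp(-t_app / gt$tau_fast) + (1 - a) * exp(-t_app / tau_slow)
    plateau <- max((r - s_end) / (1 - s_end), 0)
    times <- seq(0, t_pre + t_app, by = dt)
    t_a <- pmax(times - t_pre, 0)
    decay <- plateau + (1 - plateau) * (a * exp(-t_a / gt$tau_fast) +
                                          (1 - a) * exp(-t_a / tau_slow))
    rise <- if (config$exchange_tau > 0) {
      1 - exp(-t_a / config$exchange_tau)
    } else {
      as.numeric(times >= t_pre)
    }
    p_cond <- rise * decay
    application <- c(t_pre, t_pre + t_app)
  }
  peak_det <- config$n_channels * config$unitary_current * max(p_cond)
  sd_g <- if (is.null(config$gaussian_noise_sd)) 0.005 * peak_det else
    config$gaussian_noise_sd
  current <- if (noise) {
    with_seed(config$seed, {
      counts <- stats::rbinom(length(p_cond), config$n_channels,
                              pmin(pmax(p_cond, 0), 1))
      y <- counts * config$unitary_current
      if (sd_g > 0) y <- y + stats::rnorm(length(y), 0, sd_g)
      y
    })
  } else {
    config$n_channels * config$unitary_current * p_cond
  }
  if (noise) current <- lowpass_causal(current, config$sample_rate,
                                       config$filter_cutoff)
  tr <- new_current_trace(times, -current,
                          n_channels = config$n_channels,
                          unitary_current = config$unitary_current,
                          application = application,
                          ground_truth = ground_truth, config = config)
  tr
}

measured_targets <- function(trace, construct = "CWT") {
  obs <- fit_biexponential(trace)
  observable_targets(construct, obs$tau_fast,
                     if (isTRUE(obs$collapsed)) NA else obs$tau_slow,
                     obs$pct_A_fast, obs$pct_I_res)
}

#' Parameter-recovery experiment
#'
#' The package's validation harness: generate noisy mechanism-mode traces
#' from known ground truth, push them through the full measurement +
#' calibration pipeline, and tabulate how well the rates come back. Each
#' replicate re-measures the observables on its own noisy wild-type trace
#' and re-calibrates the four wild-type rates (initialized from the
#' noise-free solution, which is itself obtained by the same pipeline once).
#'
#' @param variant Model variant of the generating truth.
#' @param true_params The generating [rate_parameters()].
#' @param n_reps Number of replicates (>= 20 for the package's standard
#'   validation).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param config A [recording_config()].
#' @param maxit Nelder-Mead cap per replicate calibration.
#' @return Data frame with one row per replicate and parameter: `rep`,
#'   `param`, `true`, `recovered`, `rel_error`; the noise-free anchor fit is
#'   attached as attribute `"noise_free_fit"`.
#' @export
parameter_recovery_experiment <- function(variant, true_params, n_reps = 20,
                                          seed = 1,
                                          config = recording_config(),
                                          maxit = 250) {
  stopifnot(n_reps >= 1)
  gamma <- true_params$gamma_coupling
  epsilon <- true_params$epsilon_coupling
  gt <- list(variant = variant, params = true_params)
  tr0 <- generate_trace(gt, config, noise = FALSE)
  t0 <- measured_targets(tr0)
  fit0 <- calibrate_wt(variant, t0, gamma = gamma, epsilon = epsilon,
                       maxit = 400)
  par_names <- c("delta_plus", "delta_minus", "delta3_plus", "delta3_minus")
  rows <- list()
  for (r in seq_len(n_reps)) {
    cfg <- config; cfg$seed <- seed + r
    t_r <- measured_targets(generate_trace(gt, cfg))
    fit_r <- calibrate_wt(variant, t_r, gamma = gamma, epsilon = epsilon,
                          init = fit0$params, maxit = maxit,
                          presearch = FALSE, n_refine = 1)
    for (pn in par_names) {
      rows[[length(rows) + 1]] <- data.frame(
        rep = r, param = pn, true = true_params[[pn]],
        recovered = fit_r$params[[pn]],
        rel_error = fit_r$params[[pn]] / true_params[[pn]] - 1,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "noise_free_fit") <- fit0
  out
}

#' Coupling-pair recovery experiment
#'
#' Tests whether the discrete decade grid search recovers the generating
#' Model III coupling pair. The coupling constants are not identifiable from
#' the four wild-type observables alone -- several grid pairs can fit them
#' essentially perfectly -- so, exactly like the original analysis, the
#' experiment discriminates pairs on the whole construct panel (wild type,
#' single mutants and the diagnostic combinations).
#'
#' For every grid pair a candidate model is first calibrated on the
#' noise-free (ensemble-mean) panel measurements: wild-type rates from the
#' wild-type observables, mutation multipliers from the single mutants.
#' Each replicate then generates noisy traces for the full panel from the
#' true model, measures their observables, and selects the pair whose
#' calibrated panel signature explains them best (lowest summed
#' transformed-observable loss). Nuisance parameters are thus profiled on
#' the ensemble mean, and replicate noise enters through the selection --
#' which keeps 20-replicate experiments tractable at desk scale.
#'
#' @param true_params Generating [rate_parameters()] (its couplings are the
#'   truth to recover).
#' @param multipliers Named multiplier vector of the generating mutant model
#'   (as from [fit_mutation_ratios()]).
#' @param n_reps,seed,config As in [parameter_recovery_experiment()].
#' @param grid Coupling grid (default the 1--1000 decade grid).
#' @param constructs Panel used for generation and selection.
#' @return Data frame, one row per replicate: `rep`, recovered `gamma`,
#'   `epsilon`, `loss`, `correct`. Per-pair anchor calibrations are attached
#'   as attribute `"pair_signatures"`.
#' @export
coupling_recovery_experiment <- function(true_params, multipliers,
                                         n_reps = 20, seed = 1,
                                         config = recording_config(),
                                         grid = c(1, 10, 100, 1000),
                                         constructs = c("CWT", "C3", "C4",
                                                        "C5", "C45",
                                                        "C345")) {
  variant <- "III"
  profile_of <- function(cc) construct_profile(cc, multipliers)
  gen <- function(cc, cfg, noise = TRUE) {
    generate_trace(list(variant = variant, params = true_params,
                        profile = profile_of(cc)), cfg, noise = noise)
  }
  # ensemble-mean (noise-free) measurements of the panel
  mean_targets <- lapply(constructs, function(cc) {
    measured_targets(gen(cc, config, noise = FALSE), cc)
  })
  names(mean_targets) <- constructs
  pairs <- expand.grid(gamma = grid, epsilon = grid)
  signatures <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    wt_i <- calibrate_wt(variant, mean_targets$CWT, gamma = pairs$gamma[i],
                         epsilon = pairs$epsilon[i], maxit = 350)
    fit_targets <- list()
    for (cc in intersect(c("C4", "C5"), constructs)) {
      tg <- mean_targets[[cc]]
      tg$weights <- c(tau_fast = 1, tau_slow = 0, pct_A_fast = 0,
                      pct_I_res = 0)
      fit_targets[[cc]] <- tg
    }
    if ("C3" %in% constructs) fit_targets$C3 <- mean_targets$C3
    fit_i <- fit_mutation_ratios(variant, wt_i, fit_targets, maxit = 250)
    pred_i <- predictions_table(variant, wt_i$params, fit_i,
                                constructs = constructs)
    signatures[[i]] <- list(wt = wt_i, fit = fit_i, predictions = pred_i)
  }
  sig_loss <- function(pred, rep_targets) {
    tot <- 0
    for (cc in constructs) {
      row <- pred[pred$construct == cc, ]
      obs <- data.frame(tau_fast = row$tau_fast, tau_slow = row$tau_slow,
                        pct_A_fast = row$pct_A_fast,
                        pct_I_res = row$pct_I_res)
      tot <- tot + target_loss(obs, rep_targets[[cc]])
    }
    tot
  }
  rows <- list()
  for (r in seq_len(n_reps)) {
    rep_targets <- lapply(seq_along(constructs), function(j) {
      cfg <- config
      cfg$seed <- seed + r * 1000L + j
      measured_targets(gen(constructs[j], cfg), constructs[j])
    })
    names(rep_targets) <- constructs
    losses <- vapply(signatures, function(s) sig_loss(s$predictions,
                                                      rep_targets),
                     numeric(1))
    best <- which.min(losses)
    rows[[r]] <- data.frame(
      rep = r, gamma = pairs$gamma[best], epsilon = pairs$epsilon[best],
      loss = losses[best],
      correct = pairs$gamma[best] == true_params$gamma_coupling &&
        pairs$epsilon[best] == true_params$epsilon_coupling)
  }
  out <- do.call(rbind, rows)
  attr(out, "pair_signatures") <- signatures
  out
}
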