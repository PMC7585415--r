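# Master-equation propagation and conversion to macroscopic current.

#' Agonist application protocol
#'
#' A protocol is a list of segments of constant target concentration. The
#' default emulates the study condition: a 60 s step of 10 mM agonist with an
#' instantaneous concentration change, sampled at 500 Hz (dt = 2 ms).
#' `exchange_tau > 0` models solution exchange as a single-exponential
#' approach of the bath concentration toward each segment's target.
#'
#' @param durations Segment durations in seconds.
#' @param concentrations Segment target concentrations in molar.
#' @param dt Sampling interval in seconds.
#' @param exchange_tau Solution-exchange time constant in seconds (0 = ideal
#'   step). A 20--80% rise of ln(4) * exchange_tau results for a conductance
#'   linear in concentration exposure.
#' @return An object of class `agonist_protocol`.
#' @export
agonist_protocol <- function(durations = 60, concentrations = 0.01,
                             dt = 0.002, exchange_tau = 0) {
  stopifnot(length(durations) == length(concentrations),
            all(durations > 0), dt > 0, exchange_tau >= 0,
            all(concentrations >= 0))
  p <- list(segments = data.frame(duration = durations,
                                  concentration = concentrations),
            dt = dt, exchange_tau = exchange_tau,
            duration_total = sum(durations))
  class(p) <- "agonist_protocol"
  p
}

#' @export
print.agonist_protocol <- function(x, ...) {
  cat(sprintf("Agonist protocol: %d segment(s), %.4g s total, dt = %.4g s",
              nrow(x$segments), x$duration_total, x$dt))
  cat(if (x$exchange_tau > 0)
    sprintf(", exchange tau = %.4g s\n", x$exchange_tau) else
      " (ideal steps)\n")
  for (i in seq_len(nrow(x$segments))) {
    cat(sprintf("  %2d: %.4g s at %.4g M\n", i, x$segments$duration[i],
                x$segments$concentration[i]))
  }
  invisible(x)
}

# Application window = span of the segments with nonzero concentration
# (used by peak finding and %I_res).
application_window <- function(protocol) {
  seg <- protocol$segments
  ends <- cumsum(seg$duration)
  starts <- c(0, utils::head(ends, -1))
  on <- which(seg$concentration > 0)
  if (!length(on)) return(c(0, protocol$duration_total))
  c(starts[min(on)], ends[max(on)])
}

#' Propagate the master equation
#'
#' Evolves the state-occupancy distribution from all probability in the
#' resting state R, under the piecewise-constant generator defined by the
#' protocol (the generator is rebuilt whenever the concentration changes).
#' Within each constant-concentration stretch, stepping uses the matrix
#' exponential of `generator * dt`, which is exact for any dt. With
#' `exchange_tau > 0` the concentration is resampled every dt along its
#' exponential approach and the matrix exponential is recomputed while the
#' concentration is still moving; stepping accuracy is then O(dt) and a
#' warning is issued if dt exceeds the fastest state-exit time.
#'
#' @param scheme A [build_scheme()] result; its own `agonist_conc` is
#'   overridden segment by segment.
#' @param protocol An [agonist_protocol()].
#' @return An object of class `occupancy_trajectory`: list with `times`
#'   (seconds), `probabilities` (time x state matrix, rows summing to 1) and
#'   the scheme/protocol context.
#' @examples
#' sch <- build_scheme("I", rate_parameters())
#' traj <- propagate(sch, agonist_protocol(durations = 5))
#' stopifnot(all(abs(rowSums(traj$probabilities) - 1) < 1e-8))
#' @export
propagate <- function(scheme, protocol = agonist_protocol()) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(protocol, "agonist_protocol"))
  dt <- protocol$dt
  n <- nrow(scheme$states)
  nt <- round(protocol$duration_total / dt)
  times <- seq(0, by = dt, length.out = nt + 1)
  P <- matrix(NA_real_, nt + 1, n,
              dimnames = list(NULL, scheme$states$label))
  p <- c(1, rep(0, n - 1))
  P[1, ] <- p
  seg <- protocol$segments
  seg_end_steps <- round(cumsum(seg$duration) / dt)
  step <- 0L
  conc_now <- 0  # bath concentration before the protocol starts
  for (s in seq_len(nrow(seg))) {
    target <- seg$concentration[s]
    n_steps <- seg_end_steps[s] - step
    if (n_steps <= 0) next
    if (protocol$exchange_tau > 0 && abs(conc_now - target) >
        1e-12 * max(target, 1e-12)) {
      max_exit <- max(-diag(scheme_at_conc(scheme, max(conc_now,
                                                       target))$generator))
      if (dt > 1 / max_exit) {
        warning(warningCondition(paste0(
          "dt (", dt, " s) exceeds the fastest state-exit time (",
          signif(1 / max_exit, 3),
          " s); exchange resampling is O(dt)-accurate"),
          class = "gabadesens_dt_warning"))
      }
    }
    k <- 0L
    Pstep <- NULL
    while (k < n_steps) {
      if (protocol$exchange_tau > 0) {
        # concentration at the midpoint of this dt along the approach
        t_mid <- (k + 0.5) * dt
        c_mid <- target + (conc_now - target) *
          exp(-t_mid / protocol$exchange_tau)
        if (is.null(Pstep) ||
            abs(c_mid - attr(Pstep, "conc")) > 1e-6 * max(target, 1e-12)) {
          G <- scheme_at_conc(scheme, c_mid)$generator
          Pstep <- as.matrix(Matrix::expm(G * dt))
          attr(Pstep, "conc") <- c_mid
        }
      } else if (is.null(Pstep)) {
        G <- scheme_at_conc(scheme, target)$generator
        Pstep <- as.matrix(Matrix::expm(G * dt))
        attr(Pstep, "conc") <- target
      }
      p <- as.numeric(p %*% Pstep)
      k <- k + 1L
      P[step + k + 1L, ] <- p
    }
    if (protocol$exchange_tau > 0) {
      conc_now <- target + (conc_now - target) *
        exp(-n_steps * dt / protocol$exchange_tau)
    } else {
      conc_now <- target
    }
    step <- step + n_steps
  }
  traj <- list(times = times, probabilities = P, scheme = scheme,
               protocol = protocol)
  class(traj) <- "occupancy_trajectory"
  traj
}

# Fast path: occupancies of a constant-generator scheme at arbitrary times,
# via eigendecomposition of t(Q); falls back to per-interval expm stepping
# when the eigenbasis is ill-conditioned. Used by the calibration objective,
# where only a sparse quasi-logarithmic time grid is needed.
propagate_times <- function(scheme, times, p0 = NULL) {
  G <- scheme$generator
  n <- nrow(G)
  if (is.null(p0)) p0 <- c(1, rep(0, n - 1))
  A <- t(G)
  e <- tryCatch(eigen(A), error = function(err) NULL)
  ok <- FALSE
  if (!is.null(e)) {
    c0 <- tryCatch(solve(e$vectors, p0), error = function(err) NULL)
    if (!is.null(c0)) {
      recon <- Re(e$vectors %*% c0)
      ok <- max(abs(recon - p0)) < 1e-8
    }
  }
  if (ok) {
    E <- exp(outer(e$values, times))
    P <- t(Re(e$vectors %*% (E * c0)))
  } else {
    P <- matrix(NA_real_, length(times), n)
    p <- p0
    t_prev <- 0
    for (i in seq_along(times)) {
      dt <- times[i] - t_prev
      if (dt > 0) p <- as.numeric(p %*% as.matrix(Matrix::expm(G * dt)))
      P[i, ] <- p
      t_prev <- times[i]
    }
  }
  colnames(P) <- scheme$states$label
  P
}

#' Macroscopic current from an occupancy trajectory
#'
#' The macroscopic current is the summed occupancy of conducting states times
#' the number of channels and the unitary current. Inward currents are
#' negative by the voltage-clamp convention (holding below the reversal
#' potential); analyses operate on magnitudes.
#'
#' @param traj An [propagate()] result.
#' @param scheme The scheme the trajectory was computed from (defaults to the
#'   one stored in `traj`); must share the state order.
#' @param n_channels Number of channels in the cell.
#' @param unitary_current Single-channel current magnitude (current units;
#'   the default 1e-4 with 20,000 channels gives a 2 uA-scale peak).
#' @return An object of class `current_trace`: data frame with `time` and
#'   `current`, with the protocol's application window, `n_channels` and
#'   `unitary_current` as attributes.
#' @export
current_from_occupancy <- function(traj, scheme = traj$scheme,
                                   n_channels = 20000,
                                   unitary_current = 1e-4) {
  stopifnot(inherits(traj, "occupancy_trajectory"))
  if (ncol(traj$probabilities) != nrow(scheme$states) ||
      !identical(colnames(traj$probabilities), scheme$states$label)) {
    stop("trajectory and scheme state orders differ", call. = FALSE)
  }
  stopifnot(n_channels >= 0, unitary_current >= 0)
  p_open <- as.numeric(traj$probabilities[, scheme$conducting, drop = FALSE] %*%
                         rep(1, sum(scheme$conducting)))
  new_current_trace(traj$times, -n_channels * unitary_current * p_open,
                    n_channels = n_channels,
                    unitary_current = unitary_current,
                    application = application_window(traj$protocol))
}

new_current_trace <- function(times, current, n_channels = NA,
                              unitary_current = NA, application = NULL,
                              ground_truth = NULL, config = NULL) {
  tr <- data.frame(time = times, current = current)
  class(tr) <- c("current_trace", "data.frame")
  attr(tr, "n_channels") <- n_channels
  attr(tr, "unitary_current") <- unitary_current
  attr(tr, "application") <- if (is.null(application))
    range(times) else application
  if (!is.null(ground_truth)) attr(tr, "ground_truth") <- ground_truth
  if (!is.null(config)) attr(tr, "config") <- config
  tr
}

#' Sample finite-channel (binomial) noise on a trajectory
#'
#' At every time point the number of conducting channels is drawn from a
#' binomial distribution with size `n_channels` and the deterministic
#' conducting probability -- the channel-count noise of a macroscopic
#' recording from a finite ensemble (the study conditions use 10,000--30,000
#' channels per cell). The RNG state is restored on exit, so the draw is
#' reproducible for a fixed seed and leaves the caller's stream untouched.
#'
#' @inheritParams current_from_occupancy
#' @param seed Integer seed.
#' @return A `current_trace` with binomially sampled current.
#' @export
sample_channel_noise <- function(traj, scheme = traj$scheme,
                                 n_channels = 20000, seed = 1,
                                 unitary_current = 1e-4) {
  stopifnot(inherits(traj, "occupancy_trajectory"), n_channels >= 0)
  p_open <- as.numeric(traj$probabilities[, scheme$conducting, drop = FALSE] %*%
                         rep(1, sum(scheme$conducting)))
  p_open <- pmin(pmax(p_open, 0), 1)
  counts <- with_seed(seed, stats::rbinom(length(p_open), n_channels, p_open))
  new_current_trace(traj$times, -unitary_current * counts,
                    n_channels = n_channels,
                    unitary_current = unitary_current,
                    application = application_window(traj$protocol))
}

# Evaluate an expression under a fixed seed, restoring the global RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
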