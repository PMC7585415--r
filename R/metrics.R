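# Desensitization observables: peak, bi-exponential decay fit, tau_w.

#' Amplitude-weighted desensitization time constant
#'
#' `tau_w = %A_fast/100 * tau_fast + (1 - %A_fast/100) * tau_slow`, the
#' standard single-number summary of a bi-exponential desensitization decay.
#'
#' @param tau_fast,tau_slow Time constants in seconds.
#' @param pct_A_fast Fast-component amplitude share in percent.
#' @return tau_w in seconds.
#' @examples
#' tau_weighted(4.8, 24.4, 33.3)  # ~17.9 s
#' tau_weighted(2.7, 7.1, 20.0)   # ~6.2 s
#' @export
tau_weighted <- function(tau_fast, tau_slow, pct_A_fast) {
  a <- pct_A_fast / 100
  a * tau_fast + (1 - a) * tau_slow
}

#' Locate the peak current
#'
#' Finds the extremum of current magnitude inside the agonist application
#' window and reports the 20--80% rise time as a diagnostic of the solution
#' exchange. A flat (all-zero) window is flagged `no_peak` and downstream
#' fitting proceeds from the application onset.
#'
#' @param trace A `current_trace`.
#' @param window Two-element numeric, seconds; defaults to the trace's stored
#'   application window.
#' @return List with `time`, `magnitude`, `index`, `rise_20_80` (seconds, NA
#'   when undefined) and `no_peak`.
#' @export
find_peak <- function(trace, window = NULL) {
  stopifnot(inherits(trace, "current_trace"))
  if (is.null(window)) window <- attr(trace, "application")
  sel <- which(trace$time >= window[1] & trace$time <= window[2])
  if (!length(sel)) stop("empty analysis window", call. = FALSE)
  y <- abs(trace$current[sel])
  i <- which.max(y)
  peak <- y[i]
  no_peak <- !is.finite(peak) || peak <= 0
  rise <- NA_real_
  if (!no_peak && i > 1) {
    pre <- y[1:i]
    t_pre <- trace$time[sel][1:i]
    t20 <- t_pre[which(pre >= 0.2 * peak)[1]]
    t80 <- t_pre[which(pre >= 0.8 * peak)[1]]
    if (!is.na(t20) && !is.na(t80)) rise <- t80 - t20
  }
  list(time = if (no_peak) window[1] else trace$time[sel][i],
       magnitude = if (no_peak) 0 else peak,
       index = if (no_peak) sel[1] else sel[i],
       rise_20_80 = rise, no_peak = no_peak)
}

#' Extent of desensitization
#'
#' `1 - |I_res| / I_peak`, where `I_res` is the residual current at the end
#' of the agonist application: 0 for a non-desensitizing trace, 1 for
#' complete decay.
#'
#' @inheritParams find_peak
#' @return Fraction in `[0, 1]` for decaying traces.
#' @export
desensitization_extent <- function(trace, window = NULL) {
  pk <- find_peak(trace, window)
  if (pk$no_peak || pk$magnitude == 0) {
    stop("peak current is zero; extent of desensitization undefined",
         call. = FALSE)
  }
  if (is.null(window)) window <- attr(trace, "application")
  1 - residual_magnitude(trace, window) / pk$magnitude
}

# Residual current magnitude at the end of the application window, averaged
# over the trailing 1% of the window (>= 1 sample) to be robust to noise.
residual_magnitude <- function(trace, window) {
  span <- window[2] - window[1]
  sel <- which(trace$time >= window[2] - 0.01 * span &
                 trace$time <= window[2])
  if (!length(sel)) sel <- nrow(trace)
  mean(abs(trace$current[sel]))
}

#' Fit a bi-exponential desensitization decay
#'
#' Least-squares fit of the current magnitude over the decay window with
#' `|I(t)| = C + A_f exp(-(t - t0)/tau_fast) + A_s exp(-(t - t0)/tau_slow)`.
#' The nonlinear problem is solved by variable projection: for any candidate
#' time-constant pair the amplitudes are the exact linear least-squares
#' solution, and only `(log tau_fast, log tau_slow)` are searched, starting
#' from a fixed log-spaced grid and refined by Nelder-Mead. Components are
#' reported in ascending tau order. A degenerate second component (amplitude
#' share < 1% or tau ratio < 1.5, or a negative fitted amplitude) collapses
#' the fit to a mono-exponential reported with `pct_A_fast = 100` and
#' `tau_slow = NA`.
#'
#' `%I_res` is measured on the trace (residual over peak at the end of the
#' application), not taken from the fitted plateau `C`, which is returned
#' separately as a diagnostic.
#'
#' @param trace A `current_trace`.
#' @param window Fit window `(start, end)` in seconds; defaults to peak time
#'   to end of application.
#' @param max_points Cap on the number of samples entering the fit; when the
#'   window holds more, samples are taken on a logarithmic time grid from the
#'   window start (dense early, sparse late), which resolves fast components
#'   without giving the plateau overwhelming weight.
#' @return An object of class `desens_observables`: one-row data frame with
#'   `tau_fast`, `tau_slow` (s), `pct_A_fast`, `pct_I_res` (%), `tau_w` (s),
#'   `I_peak`, amplitudes `A_fast`, `A_slow`, fitted `plateau`,
#'   `fit_quality` (residual norm), `rise_20_80` and `collapsed`.
#' @export
fit_biexponential <- function(trace, window = NULL, max_points = 2000) {
  stopifnot(inherits(trace, "current_trace"))
  app <- attr(trace, "application")
  pk <- find_peak(trace)
  if (is.null(window)) window <- c(pk$time, app[2])
  if (pk$no_peak) window[1] <- app[1]
  sel <- which(trace$time >= window[1] & trace$time <= window[2])
  if (length(sel) < 5) stop("too few samples in fit window", call. = FALSE)
  tt <- trace$time[sel] - trace$time[sel[1]]
  yy <- abs(trace$current[sel])
  if (length(sel) > max_points) {
    idx <- unique(round(exp(seq(0, log(length(sel)), length.out = max_points))))
    tt <- tt[idx]; yy <- yy[idx]
  }
  scale <- max(yy)
  if (scale <= 0) stop("flat zero trace; nothing to fit", call. = FALSE)
  y <- yy / scale
  fit <- biexp_varpro(tt, y)
  collapsed <- FALSE
  if (fit$degenerate) {
    fit <- monoexp_varpro(tt, y)
    collapsed <- TRUE
  }
  I_peak <- pk$magnitude
  pct_I_res <- 100 * residual_magnitude(trace, app) / I_peak
  if (collapsed) {
    tau_fast <- fit$tau; tau_slow <- NA_real_
    A_fast <- fit$A * scale; A_slow <- 0
    pct_A_fast <- 100
    tau_w <- tau_fast
  } else {
    tau_fast <- fit$tau[1]; tau_slow <- fit$tau[2]
    A_fast <- fit$A[1] * scale; A_slow <- fit$A[2] * scale
    pct_A_fast <- 100 * A_fast / (A_fast + A_slow)
    tau_w <- tau_weighted(tau_fast, tau_slow, pct_A_fast)
  }
  obs <- data.frame(tau_fast = tau_fast, tau_slow = tau_slow,
                    pct_A_fast = pct_A_fast, pct_I_res = pct_I_res,
                    tau_w = tau_w, I_peak = I_peak,
                    A_fast = A_fast, A_slow = A_slow,
                    plateau = fit$C * scale,
                    fit_quality = sqrt(fit$rss) * scale,
                    rise_20_80 = pk$rise_20_80, collapsed = collapsed)
  class(obs) <- c("desens_observables", "data.frame")
  obs
}

# Profiled (variable-projection) residual sum of squares for a tau pair.
biexp_rss <- function(ltau, tt, y) {
  tau <- exp(ltau)
  X <- cbind(1, exp(-tt / tau[1]), exp(-tt / tau[2]))
  f <- tryCatch(stats::.lm.fit(X, y), error = function(e) NULL)
  if (is.null(f)) return(list(rss = Inf))
  list(rss = sum(f$residuals^2), coef = f$coefficients)
}

biexp_varpro <- function(tt, y) {
  span <- max(tt)
  tf_grid <- span * c(0.002, 0.008, 0.03, 0.1, 0.3)
  ratio_grid <- c(3, 8, 25)
  starts <- expand.grid(tf = tf_grid, ratio = ratio_grid)
  best <- NULL; best_rss <- Inf
  for (i in seq_len(nrow(starts))) {
    lt <- log(c(starts$tf[i], starts$tf[i] * starts$ratio[i]))
    r <- biexp_rss(lt, tt, y)
    if (r$rss < best_rss) { best_rss <- r$rss; best <- lt }
  }
  opt <- stats::optim(best, function(p) biexp_rss(p, tt, y)$rss,
                      method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-12))
  r <- biexp_rss(opt$par, tt, y)
  tau <- exp(opt$par)
  ord <- order(tau)
  tau <- tau[ord]
  A <- r$coef[-1][ord]
  C <- r$coef[1]
  share <- if (sum(A) != 0) min(A) / sum(A) else 0
  degenerate <- any(A < 0) || !all(is.finite(tau)) ||
    share < 0.01 || tau[2] / tau[1] < 1.5
  list(tau = tau, A = A, C = C, rss = r$rss, degenerate = degenerate)
}

monoexp_varpro <- function(tt, y) {
  span <- max(tt)
  rss1 <- function(lt) {
    X <- cbind(1, exp(-tt / exp(lt)))
    f <- stats::.lm.fit(X, y)
    sum(f$residuals^2)
  }
  opt <- stats::optimize(rss1, log(span * c(5e-4, 2)), tol = 1e-10)
  X <- cbind(1, exp(-tt / exp(opt$minimum)))
  f <- stats::.lm.fit(X, y)
  list(tau = exp(opt$minimum), A = f$coefficients[2], C = f$coefficients[1],
       rss = sum(f$residuals^2), degenerate = FALSE)
}

#' @export
print.desens_observables <- function(x, ...) {
  cat("Desensitization observables:\n")
  cat(sprintf("  tau_fast = %.4g s, tau_slow = %s s, %%A_fast = %.3g%%\n",
              x$tau_fast,
              if (is.na(x$tau_slow)) "NA (mono-exponential)" else
                sprintf("%.4g", x$tau_slow),
              x$pct_A_fast))
  cat(sprintf("  %%I_res = %.3g%%, tau_w = %.4g s, I_peak = %.4g\n",
              x$pct_I_res, x$tau_w, x$I_peak))
  invisible(x)
}
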