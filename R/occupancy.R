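# State-occupancy analysis: time courses and the kinetically favored pathway.

#' Occupancy time courses of the gated states
#'
#' Propagates the scheme under the protocol and returns the occupancy of
#' every gated (agonist-bound, channel-gated) state together with the summed
#' conducting ("active") occupancy -- the ingredients of the classic plot
#' comparing the active population with the rise and fall of each
#' desensitized state.
#'
#' @inheritParams propagate
#' @return Data frame with `time`, one column per gated state, and `active`
#'   (summed conducting occupancy). The full trajectory is attached as
#'   attribute `"trajectory"`.
#' @export
occupancy_timecourses <- function(scheme, protocol = agonist_protocol()) {
  traj <- propagate(scheme, protocol)
  gated <- scheme$states$label[scheme$states$tag == "GATED"]
  out <- data.frame(time = traj$times)
  for (g in gated) out[[g]] <- traj$probabilities[, g]
  out$active <- rowSums(traj$probabilities[, scheme$conducting,
                                           drop = FALSE])
  attr(out, "trajectory") <- traj
  out
}

#' Kinetically favored desensitization pathway
#'
#' Operationalizes "the pathway the receptors actually take": every
#' desensitization edge is assigned its cumulative probability flux
#' `integral( rate * occupancy(source) dt )` over the application, and a
#' greedy walk from AO follows the maximum-flux outgoing desensitization
#' edge until the terminal (all-desensitized) state is reached or no forward
#' flux remains. Ties (edges within relative tolerance of the maximum, e.g.
#' the symmetric SU4/SU5 first step of a wild-type scheme) are reported as
#' co-dominant rather than silently broken; the walk continues through the
#' canonically first of the tied states.
#'
#' @inheritParams propagate
#' @param traj Optional precomputed [propagate()] trajectory.
#' @param tie_tol Relative tolerance under which competing edge fluxes are
#'   reported as tied.
#' @return An object of class `pathway_report`: list with `path` (state
#'   labels from AO onward), `edges` (data frame: from, to, subunit, flux,
#'   co-dominant alternatives), `peaks` (per-state peak occupancy and time)
#'   and the full per-edge `flux_table`.
#' @export
dominant_pathway <- function(scheme, protocol = agonist_protocol(),
                             traj = NULL, tie_tol = 1e-6) {
  if (is.null(traj)) traj <- propagate(scheme, protocol)
  tbl <- scheme$transitions
  des <- which(tbl$kind == "desens")
  dt_w <- trapezoid_weights(traj$times)
  flux <- vapply(des, function(k) {
    occ <- traj$probabilities[, tbl$from_idx[k]]
    tbl$rate[k] * sum(dt_w * occ)
  }, numeric(1))
  flux_table <- data.frame(from = tbl$from[des], to = tbl$to[des],
                           subunit = tbl$subunit[des], flux = flux,
                           stringsAsFactors = FALSE)
  gated <- scheme$states$label[scheme$states$tag == "GATED"]
  peaks <- do.call(rbind, lapply(gated, function(g) {
    occ <- traj$probabilities[, g]
    i <- which.max(occ)
    data.frame(state = g, peak_occupancy = occ[i],
               peak_time = traj$times[i], stringsAsFactors = FALSE)
  }))
  path <- "AO"
  edges <- NULL
  current <- "AO"
  visited <- character()
  repeat {
    visited <- c(visited, current)
    out <- flux_table[flux_table$from == current &
                        !(flux_table$to %in% visited), , drop = FALSE]
    out <- out[out$flux > 0, , drop = FALSE]
    if (!nrow(out)) break
    fmax <- max(out$flux)
    tied <- out$to[out$flux >= fmax * (1 - tie_tol)]
    nxt <- sort(tied)[1]   # canonical continuation through the first tied
    edges <- rbind(edges, data.frame(
      from = current, to = nxt,
      subunit = out$subunit[out$to == nxt],
      flux = out$flux[out$to == nxt],
      co_dominant = paste(setdiff(sort(tied), nxt), collapse = ","),
      stringsAsFactors = FALSE))
    path <- c(path, nxt)
    current <- nxt
  }
  rep_out <- list(path = path, edges = edges, peaks = peaks,
                  flux_table = flux_table)
  class(rep_out) <- "pathway_report"
  rep_out
}

trapezoid_weights <- function(times) {
  n <- length(times)
  d <- diff(times)
  c(d[1] / 2, (d[-(n - 1)] + d[-1]) / 2, d[n - 1] / 2)
}

#' @export
print.pathway_report <- function(x, ...) {
  cat("Kinetically favored desensitization pathway:\n  ",
      paste(x$path, collapse = " -> "), "\n", sep = "")
  if (!is.null(x$edges)) {
    ties <- x$edges$co_dominant != ""
    if (any(ties)) {
      for (i in which(ties)) {
        cat(sprintf("  (step %s -> %s co-dominant with %s)\n",
                    x$edges$from[i], x$edges$to[i], x$edges$co_dominant[i]))
      }
    }
  }
  invisible(x)
}
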