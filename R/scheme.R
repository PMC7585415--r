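# Scheme assembly: states + transition table -> generator (Q) matrix.
# The transition table is built once per topology; rates are recomputed from
# (params, profile, variant, [A]) by transition_rates(), which keeps repeated
# rebuilds during calibration cheap.

scheme_transitions <- function(states) {
  idx <- stats::setNames(seq_len(nrow(states)), states$label)
  from <- character(); to <- character(); kind <- character()
  subunit <- character(); ctx <- list()
  add <- function(f, t, k, su = NA_character_, cx = character()) {
    from <<- c(from, f); to <<- c(to, t); kind <<- c(kind, k)
    subunit <<- c(subunit, su); ctx[[length(ctx) + 1]] <<- cx
  }
  add("R", "AR", "bind")
  add("AR", "R", "unbind")
  add("AR", "AO", "open")
  add("AO", "AR", "close")
  gated <- which(states$tag == "GATED")
  desensitizable <- attr(states, "desensitizable")
  for (i in gated) {
    p <- states$pattern[[i]]
    for (su in setdiff(desensitizable, p)) {
      q <- sort(c(p, su))
      # ctx = conformation of the other subunits, shared by both directions
      add(states$label[i], pattern_label(q), "desens", su, p)
      add(pattern_label(q), states$label[i], "recover", su, p)
    }
  }
  tbl <- data.frame(from = from, to = to, kind = kind, subunit = subunit,
                    stringsAsFactors = FALSE)
  tbl$ctx <- ctx
  tbl$from_idx <- idx[tbl$from]
  tbl$to_idx <- idx[tbl$to]
  tbl
}

delta_of <- function(params, su, side) {
  if (su == "SU3") {
    if (side == "plus") params$delta3_plus else params$delta3_minus
  } else {
    if (side == "plus") params$delta_plus else params$delta_minus
  }
}

mult_of <- function(profile, su, side) {
  i <- sub("SU", "", su)
  if (!(i %in% c("3", "4", "5"))) return(1)
  profile[[paste0("c", i, "_", side)]]
}

transition_rates <- function(tbl, params, profile, variant, agonist_conc) {
  n <- nrow(tbl)
  r <- numeric(n)
  for (k in seq_len(n)) {
    kind <- tbl$kind[k]
    if (kind == "bind") { r[k] <- params$k_on * agonist_conc; next }
    if (kind == "unbind") { r[k] <- params$k_off; next }
    if (kind == "open") { r[k] <- params$beta; next }
    if (kind == "close") { r[k] <- params$alpha; next }
    su <- tbl$subunit[k]
    ctx <- tbl$ctx[[k]]
    side <- if (kind == "desens") "plus" else "minus"
    rate <- delta_of(params, su, side)
    if (su %in% profile$mutated) rate <- rate * mult_of(profile, su, side)
    if (variant %in% c("II_BETA", "III") && su == "SU4" &&
        "SU3" %in% profile$mutated) {
      rate <- rate * (if (side == "plus") profile$c34_plus else
                        profile$c34_minus)
    }
    if (variant == "III") {
      if (kind == "desens") {
        # gamma: SU3 and SU4 mutually accelerate each other's desensitization
        if ((su == "SU3" && "SU4" %in% ctx) ||
            (su == "SU4" && "SU3" %in% ctx)) {
          rate <- rate * params$gamma_coupling
        }
      } else {
        # epsilon: SU4 and SU5 mutually slow each other's recovery
        if ((su == "SU5" && "SU4" %in% ctx) ||
            (su == "SU4" && "SU5" %in% ctx)) {
          rate <- rate / params$epsilon_coupling
        }
      }
    }
    r[k] <- rate
  }
  r
}

#' Effective rate of a single elementary transition
#'
#' Computes the rate of one allowed transition (agonist binding/unbinding,
#' channel gating, or a single subunit's desensitization flip) after applying
#' mutation multipliers and, for Model III, the inter-subunit couplings.
#' The coupling rules are: desensitization of SU3 is accelerated by
#' `gamma_coupling` when SU4 is already desensitized and vice versa; recovery
#' of SU5 is slowed by `epsilon_coupling` when SU4 is desensitized and vice
#' versa. Under Models II-beta and III, when SU3 is mutated SU4's rates are
#' additionally multiplied by `c34_plus`/`c34_minus`.
#'
#' @param from,to State labels (e.g. `"AO"`, `"AD4"`, `"AD34"`) from a scheme
#'   with the given desensitizable set.
#' @param params A [rate_parameters()] object.
#' @param profile A [mutation_profile()].
#' @param variant One of `"I"`, `"II"`, `"II_BETA"`, `"III"` (the CONCERTED
#'   variant has its own fixed five-state wiring, see [build_scheme()]).
#' @param agonist_conc Agonist concentration in molar (used by `R -> AR`).
#' @param desensitizable Desensitizable subunit set defining the topology.
#' @return The transition rate in per second.
#' @examples
#' p <- rate_parameters(gamma_coupling = 100, epsilon_coupling = 10)
#' effective_rate("AD4", "AD34", p, mutation_profile(), "III")  # gamma*delta3+
#' effective_rate("AD45", "AD4", p, mutation_profile(), "III")  # delta-/epsilon
#' @export
effective_rate <- function(from, to, params, profile = mutation_profile(),
                           variant = "III", agonist_conc = 0.01,
                           desensitizable = default_desensitizable()) {
  variant <- check_variant(variant)
  if (variant == "CONCERTED") {
    stop("effective_rate() addresses the subunit-resolved variants; ",
         "use build_scheme() for CONCERTED", call. = FALSE)
  }
  states <- enumerate_states(desensitizable, variant)
  tbl <- scheme_transitions(states)
  hit <- which(tbl$from == from & tbl$to == to)
  if (!length(hit)) {
    stop("states ", from, " and ", to, " are not connected by an ",
         "elementary transition", call. = FALSE)
  }
  transition_rates(tbl[hit, , drop = FALSE], params, profile, variant,
                   agonist_conc)
}

#' Assemble a kinetic scheme
#'
#' Builds the full Markov scheme for a model variant: the ordered state list,
#' the elementary transition list with effective rates, and the generator
#' (Q) matrix whose off-diagonal entries are state-to-state rates and whose
#' rows sum to zero.
#'
#' For the CONCERTED variant the states are `R, AR, AO, Dfast, Dslow` with the
#' two desensitized states as parallel nonconducting branches off AO;
#' `delta_plus`/`delta_minus` are the fast-state entry/exit rates,
#' `delta3_plus`/`delta3_minus` the slow-state ones. A mutated subunit
#' multiplies entry/exit of the fast state by its `(gamma_f, epsilon_f)` and
#' of the slow state by its `(gamma_s, epsilon_s)` concerted factors;
#' combined mutants multiply the factors of all mutated subunits.
#'
#' @inheritParams effective_rate
#' @return An object of class `kinetic_scheme`: list with `states`,
#'   `transitions` (from, to, rate, descriptor), `generator`, `conducting`
#'   (logical per state) and the build context.
#' @examples
#' sch <- build_scheme("III", rate_parameters(gamma_coupling = 100,
#'                                            epsilon_coupling = 10))
#' range(rowSums(sch$generator))   # ~0: probability conservation
#' @export
build_scheme <- function(variant, params, profile = mutation_profile(),
                         agonist_conc = 0.01,
                         desensitizable = default_desensitizable()) {
  variant <- check_variant(variant)
  stopifnot(inherits(params, "rate_parameters"),
            inherits(profile, "mutation_profile"))
  if (agonist_conc < 0 || !is.finite(agonist_conc)) {
    stop("agonist_conc must be finite and >= 0", call. = FALSE)
  }
  if (variant == "CONCERTED") {
    return(build_concerted_scheme(params, profile, agonist_conc))
  }
  states <- enumerate_states(desensitizable, variant)
  tbl <- scheme_transitions(states)
  tbl$rate <- transition_rates(tbl, params, profile, variant, agonist_conc)
  scheme_from_table(variant, states, tbl, params, profile, agonist_conc,
                    desensitizable)
}

build_concerted_scheme <- function(params, profile, agonist_conc) {
  labels <- c("R", "AR", "AO", "Dfast", "Dslow")
  states <- data.frame(label = labels,
                       tag = c("R", "AR", "GATED", "GATED", "GATED"),
                       stringsAsFactors = FALSE)
  states$pattern <- list(character(), character(), character(),
                         "Dfast", "Dslow")
  states$n_desens <- c(NA, NA, 0L, 1L, 1L)
  states$conducting <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  attr(states, "desensitizable") <- character()
  fac <- c(gf = 1, ef = 1, gs = 1, es = 1)
  for (su in profile$mutated) {
    f <- profile$concerted_factors[[su]]
    if (!is.null(f)) fac <- fac * f
  }
  tbl <- data.frame(
    from = c("R", "AR", "AR", "AO", "AO", "Dfast", "AO", "Dslow"),
    to = c("AR", "R", "AO", "AR", "Dfast", "AO", "Dslow", "AO"),
    kind = c("bind", "unbind", "open", "close",
             "desens", "recover", "desens", "recover"),
    subunit = c(NA, NA, NA, NA, "Dfast", "Dfast", "Dslow", "Dslow"),
    stringsAsFactors = FALSE)
  tbl$ctx <- rep(list(character()), nrow(tbl))
  idx <- stats::setNames(seq_len(nrow(states)), states$label)
  tbl$from_idx <- idx[tbl$from]; tbl$to_idx <- idx[tbl$to]
  tbl$rate <- c(params$k_on * agonist_conc, params$k_off,
                params$beta, params$alpha,
                params$delta_plus * fac[["gf"]],
                params$delta_minus * fac[["ef"]],
                params$delta3_plus * fac[["gs"]],
                params$delta3_minus * fac[["es"]])
  scheme_from_table("CONCERTED", states, tbl, params, profile, agonist_conc,
                    character())
}

scheme_from_table <- function(variant, states, tbl, params, profile,
                              agonist_conc, desensitizable) {
  n <- nrow(states)
  G <- matrix(0, n, n, dimnames = list(states$label, states$label))
  for (k in seq_len(nrow(tbl))) {
    G[tbl$from_idx[k], tbl$to_idx[k]] <- G[tbl$from_idx[k], tbl$to_idx[k]] +
      tbl$rate[k]
  }
  diag(G) <- diag(G) - rowSums(G)
  if (any(!is.finite(G))) stop("non-finite generator entries", call. = FALSE)
  sch <- list(variant = variant, states = states, transitions = tbl,
              generator = G, conducting = states$conducting,
              params = params, profile = profile,
              agonist_conc = agonist_conc, desensitizable = desensitizable)
  class(sch) <- "kinetic_scheme"
  sch
}

# Rebuild the generator at a different agonist concentration. Only the
# R -> AR binding rate depends on [A], so this is a cheap patch.
scheme_at_conc <- function(scheme, conc) {
  if (conc == scheme$agonist_conc) return(scheme)
  G <- scheme$generator
  old <- scheme$params$k_on * scheme$agonist_conc
  new <- scheme$params$k_on * conc
  G["R", "AR"] <- G["R", "AR"] - old + new
  G["R", "R"] <- G["R", "R"] + old - new
  scheme$generator <- G
  scheme$agonist_conc <- conc
  k <- which(scheme$transitions$kind == "bind")
  scheme$transitions$rate[k] <- new
  scheme
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("Kinetic scheme, model %s: %d states, %d transitions\n",
              x$variant, nrow(x$states), nrow(x$transitions)))
  cat("  conducting:", paste(x$states$label[x$conducting], collapse = ", "),
      "\n")
  cat(sprintf("  agonist %.3g M; mutated: %s\n", x$agonist_conc,
              if (length(x$profile$mutated))
                paste(x$profile$mutated, collapse = ",") else "none"))
  invisible(x)
}

#' Export the scheme as an edge list
#'
#' @param scheme A [build_scheme()] result.
#' @return Data frame with `from`, `to`, `rate` (per second) and a human
#'   readable `descriptor` per elementary transition, suitable for
#'   `write.table()`.
#' @export
scheme_edges <- function(scheme) {
  tbl <- scheme$transitions
  desc <- ifelse(tbl$kind %in% c("bind", "unbind", "open", "close"),
                 tbl$kind, paste(tbl$kind, tbl$subunit, sep = ":"))
  data.frame(from = tbl$from, to = tbl$to, rate = tbl$rate,
             descriptor = desc, stringsAsFactors = FALSE)
}

#' Check detailed balance on the desensitization layer
#'
#' Every pair of subunits that can flip in either order from a common gated
#' state spans a 4-cycle (e.g. AO -> AD4 -> AD45 -> AD5 -> AO). Thermodynamic
#' consistency requires the product of rates clockwise around each such cycle
#' to equal the counter-clockwise product; the placement of the gamma/epsilon
#' couplings and of the mutation multipliers preserves this for every variant
#' and profile.
#'
#' @param scheme A [build_scheme()] result (non-concerted variant).
#' @param rtol Relative tolerance on the ratio of cycle products.
#' @return Data frame, one row per 4-cycle: the four states, both products
#'   and a `violated` flag. Attribute `n_violations` gives the count.
#' @export
check_detailed_balance <- function(scheme, rtol = 1e-9) {
  states <- scheme$states
  G <- scheme$generator
  desensitizable <- scheme$desensitizable
  rows <- list()
  gated <- which(states$tag == "GATED")
  for (i in gated) {
    p <- states$pattern[[i]]
    free <- setdiff(desensitizable, p)
    if (length(free) < 2) next
    pairs <- utils::combn(free, 2, simplify = FALSE)
    for (pr in pairs) {
      a <- pattern_label(sort(c(p, pr[1])))
      b <- pattern_label(sort(c(p, pr)))
      d <- pattern_label(sort(c(p, pr[2])))
      s <- states$label[i]
      cw <- G[s, a] * G[a, b] * G[b, d] * G[d, s]
      ccw <- G[s, d] * G[d, b] * G[b, a] * G[a, s]
      rows[[length(rows) + 1]] <- data.frame(
        base = s, via1 = a, opposite = b, via2 = d,
        product_cw = cw, product_ccw = ccw,
        violated = abs(cw - ccw) > rtol * max(abs(cw), abs(ccw), 1e-300),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(base = character(), via1 = character(), opposite = character(),
               via2 = character(), product_cw = numeric(),
               product_ccw = numeric(), violated = logical())
  attr(out, "n_violations") <- sum(out$violated)
  out
}
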