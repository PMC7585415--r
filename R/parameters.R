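#' Kinetic rate parameters
#'
#' Container for the elementary rate constants of the desensitization schemes.
#' Binding and gating defaults are fixed at values broadly consistent with
#' published GABA-A receptor kinetics and chosen so that, at the 10 mM agonist
#' concentration used throughout, activation equilibrates in well under
#' 100 ms -- two orders of magnitude faster than the second-scale
#' desensitization it feeds. The fitted desensitization observables are then
#' insensitive to the exact activation rates (jointly scaling beta and alpha
#' tenfold shifts the fitted time constants by under 2%).
#'
#' For the non-concerted variants `delta3_plus`/`delta3_minus` are SU3's
#' desensitization and recovery rates while `delta_plus`/`delta_minus` are
#' shared by SU4 and SU5 (the two constructs mutated there have
#' indistinguishable phenotypes, so their rates are set equal). For the
#' CONCERTED variant the same four slots are reused as the entry/exit rates of
#' the fast (`delta_plus`/`delta_minus`) and slow
#' (`delta3_plus`/`delta3_minus`) global desensitized states.
#'
#' `gamma_coupling` and `epsilon_coupling` are the Model III inter-subunit
#' couplings: desensitization of SU3 accelerates desensitization of SU4 by
#' `gamma_coupling` and vice versa; desensitization of SU4 slows recovery of
#' SU5 by `epsilon_coupling` and vice versa. Both are dimensionless and >= 1
#' (1 = no coupling; Models I/II/II-beta ignore them).
#'
#' @param k_on Agonist association rate, per molar per second.
#' @param k_off Agonist dissociation rate, per second.
#' @param beta Channel opening rate, per second.
#' @param alpha Channel closing rate, per second. Gating efficacy E = beta /
#'   alpha is derived, never stored.
#' @param delta3_plus,delta3_minus SU3 (or slow-state) desensitization and
#'   recovery rates, per second.
#' @param delta_plus,delta_minus SU4/SU5 (or fast-state) desensitization and
#'   recovery rates, per second.
#' @param gamma_coupling,epsilon_coupling Dimensionless couplings >= 1.
#' @return An object of class `rate_parameters` (named list).
#' @examples
#' p <- rate_parameters(delta_plus = 0.2, delta_minus = 1,
#'                      delta3_plus = 0.04, delta3_minus = 0.006)
#' gating_efficacy(p)  # beta / alpha = 10
#' @export
rate_parameters <- function(k_on = 1e6, k_off = 1e3, beta = 200, alpha = 20,
                            delta3_plus = 0.04, delta3_minus = 0.01,
                            delta_plus = 0.2, delta_minus = 1,
                            gamma_coupling = 1, epsilon_coupling = 1) {
  p <- list(k_on = k_on, k_off = k_off, beta = beta, alpha = alpha,
            delta3_plus = delta3_plus, delta3_minus = delta3_minus,
            delta_plus = delta_plus, delta_minus = delta_minus,
            gamma_coupling = gamma_coupling,
            epsilon_coupling = epsilon_coupling)
  rates <- unlist(p[1:8])
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("all rate constants must be finite and > 0", call. = FALSE)
  }
  if (gamma_coupling < 1 || epsilon_coupling < 1) {
    stop("coupling constants must be >= 1", call. = FALSE)
  }
  class(p) <- "rate_parameters"
  p
}

#' @rdname rate_parameters
#' @param params A `rate_parameters` object.
#' @export
gating_efficacy <- function(params) params$beta / params$alpha

#' @export
print.rate_parameters <- function(x, ...) {
  cat("Rate parameters (s^-1 unless noted):\n")
  cat(sprintf("  binding : k_on = %.3g /M/s, k_off = %.3g\n", x$k_on, x$k_off))
  cat(sprintf("  gating  : beta = %.3g, alpha = %.3g (E = %.3g)\n",
              x$beta, x$alpha, gating_efficacy(x)))
  cat(sprintf("  SU3/slow: delta3+ = %.4g, delta3- = %.4g\n",
              x$delta3_plus, x$delta3_minus))
  cat(sprintf("  SU4,SU5/fast: delta+ = %.4g, delta- = %.4g\n",
              x$delta_plus, x$delta_minus))
  cat(sprintf("  couplings: gamma = %.3g, epsilon = %.3g\n",
              x$gamma_coupling, x$epsilon_coupling))
  invisible(x)
}

#' Mutation profile
#'
#' Describes which subunits carry the gain-of-desensitization mutation and how
#' the mutation rescales the elementary rates. `c<i>_plus` multiplies subunit
#' i's desensitization rate and `c<i>_minus` its recovery rate;
#' `c34_plus`/`c34_minus` are the cross effect of the SU3 mutation on SU4's
#' rates (active under Models II-beta and III only). Multipliers of unmutated
#' subunits must equal 1.
#'
#' For the CONCERTED variant, `concerted_factors` holds one quadruple
#' `c(gamma_f, epsilon_f, gamma_s, epsilon_s)` per mutated subunit: the
#' multiplicative effect of that subunit's mutation on fast-state entry/exit
#' and slow-state entry/exit. Combining mutations multiplies the factors
#' (i.e. free-energy contributions add).
#'
#' @param mutated Character vector of mutated subunits (subset of SU1..SU5).
#' @param c3_plus,c3_minus,c4_plus,c4_minus,c5_plus,c5_minus Dimensionless
#'   multipliers > 0.
#' @param c34_plus,c34_minus Cross-effect multipliers > 0.
#' @param concerted_factors Named list (names = mutated subunits) of numeric
#'   quadruples `(gamma_f, epsilon_f, gamma_s, epsilon_s)`.
#' @return An object of class `mutation_profile`.
#' @examples
#' wt <- mutation_profile()
#' c45 <- mutation_profile(c("SU4", "SU5"), c4_plus = 12, c5_plus = 12)
#' @export
mutation_profile <- function(mutated = character(),
                             c3_plus = 1, c3_minus = 1,
                             c4_plus = 1, c4_minus = 1,
                             c5_plus = 1, c5_minus = 1,
                             c34_plus = 1, c34_minus = 1,
                             concerted_factors = list()) {
  check_subunits(mutated)
  mutated <- sort(unique(mutated))
  m <- list(mutated = mutated,
            c3_plus = c3_plus, c3_minus = c3_minus,
            c4_plus = c4_plus, c4_minus = c4_minus,
            c5_plus = c5_plus, c5_minus = c5_minus,
            c34_plus = c34_plus, c34_minus = c34_minus,
            concerted_factors = concerted_factors)
  mult <- unlist(m[2:9])
  if (any(!is.finite(mult)) || any(mult <= 0)) {
    stop("mutation multipliers must be finite and > 0", call. = FALSE)
  }
  for (su in c("SU3", "SU4", "SU5")) {
    i <- sub("SU", "", su)
    if (!(su %in% mutated)) {
      if (m[[paste0("c", i, "_plus")]] != 1 ||
          m[[paste0("c", i, "_minus")]] != 1) {
        stop("multipliers of unmutated subunit ", su, " must equal 1",
             call. = FALSE)
      }
    }
  }
  if (!("SU3" %in% mutated) && (c34_plus != 1 || c34_minus != 1)) {
    stop("c34 multipliers require SU3 to be mutated", call. = FALSE)
  }
  if (length(concerted_factors)) {
    if (is.null(names(concerted_factors)) ||
        !all(names(concerted_factors) %in% mutated)) {
      stop("concerted_factors must be named after mutated subunits",
           call. = FALSE)
    }
    ok <- vapply(concerted_factors, function(f) {
      length(f) == 4 && all(is.finite(f)) && all(f > 0)
    }, logical(1))
    if (!all(ok)) {
      stop("each concerted factor must be 4 positive numbers", call. = FALSE)
    }
  }
  class(m) <- "mutation_profile"
  m
}

#' @export
print.mutation_profile <- function(x, ...) {
  if (!length(x$mutated)) {
    cat("Mutation profile: wild type\n")
    return(invisible(x))
  }
  cat("Mutation profile: mutated", paste(x$mutated, collapse = ", "), "\n")
  for (i in c(3, 4, 5)) {
    cp <- x[[paste0("c", i, "_plus")]]
    cm <- x[[paste0("c", i, "_minus")]]
    if (cp != 1 || cm != 1) {
      cat(sprintf("  c%d+ = %.4g, c%d- = %.4g\n", i, cp, i, cm))
    }
  }
  if (x$c34_plus != 1 || x$c34_minus != 1) {
    cat(sprintf("  c34+ = %.4g, c34- = %.4g\n", x$c34_plus, x$c34_minus))
  }
  for (su in names(x$concerted_factors)) {
    f <- x$concerted_factors[[su]]
    cat(sprintf("  %s concerted (gf, ef, gs, es) = %s\n", su,
                paste(signif(f, 4), collapse = ", ")))
  }
  invisible(x)
}

#' Mutation profile of a named concatemer construct
#'
#' Maps a construct label such as `"C45"` (subunits 4 and 5 mutated) onto a
#' [mutation_profile()], applying per-subunit multipliers from a fitted
#' multiplier set. Combination constructs inherit the single-mutant
#' multipliers unchanged: combining mutations is the multiplicative
#' (free-energy additive) null model whose failure or success is the object of
#' the model comparison.
#'
#' @param construct Label: `"CWT"` or `"C"` followed by mutated subunit
#'   digits, e.g. `"C3"`, `"C45"`, `"C345"`.
#' @param multipliers Named numeric vector of fitted multipliers (names among
#'   `c3_plus`, `c3_minus`, `c4_plus`, `c4_minus`, `c5_plus`, `c5_minus`,
#'   `c34_plus`, `c34_minus`), applied only for subunits the construct
#'   actually mutates.
#' @param concerted_factors Named list of per-subunit quadruples for the
#'   CONCERTED variant (see [mutation_profile()]).
#' @return A `mutation_profile`.
#' @examples
#' construct_profile("C45", c(c4_plus = 12, c5_plus = 12))
#' @export
construct_profile <- function(construct, multipliers = numeric(),
                              concerted_factors = list()) {
  mutated <- construct_mutated(construct)
  args <- list(mutated = mutated)
  for (i in intersect(c("3", "4", "5"), sub("SU", "", mutated))) {
    for (side in c("plus", "minus")) {
      nm <- paste0("c", i, "_", side)
      if (nm %in% names(multipliers)) args[[nm]] <- unname(multipliers[nm])
    }
  }
  if ("SU3" %in% mutated) {
    for (nm in c("c34_plus", "c34_minus")) {
      if (nm %in% names(multipliers)) args[[nm]] <- unname(multipliers[nm])
    }
  }
  if (length(concerted_factors)) {
    args$concerted_factors <- concerted_factors[
      intersect(names(concerted_factors), mutated)]
  }
  do.call(mutation_profile, args)
}

construct_mutated <- function(construct) {
  if (construct %in% c("CWT", "WT", "C")) return(character())
  digits <- strsplit(sub("^C", "", construct), "")[[1]]
  if (!length(digits) || !all(digits %in% as.character(1:5))) {
    stop("cannot parse construct label: ", construct, call. = FALSE)
  }
  paste0("SU", sort(unique(digits)))
}
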