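#' Subunit identifiers of the concatemeric pentamer
#'
#' The pentamer is a single-polypeptide concatemer in the fixed arrangement
#' beta2--alpha1--beta2--alpha1--gamma2, numbered SU1..SU5 counter-clockwise
#' as seen from the extracellular space. The reduced kinetic schemes let only
#' SU3, SU4 and SU5 desensitize: these three subunits carry essentially all of
#' the mutant phenotypes, and restricting the desensitization layer to them
#' reduces the state space from 34 to 10 states.
#'
#' @return Character vector `c("SU1", ..., "SU5")`.
#' @export
subunit_ids <- function() paste0("SU", 1:5)

#' @rdname subunit_ids
#' @param subunit Character vector of subunit labels.
#' @return `subunit_role()`: the subunit class ("beta2", "alpha1" or "gamma2")
#'   of each label.
#' @export
subunit_role <- function(subunit) {
  roles <- c(SU1 = "beta2", SU2 = "alpha1", SU3 = "beta2",
             SU4 = "alpha1", SU5 = "gamma2")
  check_subunits(subunit)
  unname(roles[subunit])
}

#' Default desensitizable subunit set
#' @return `c("SU3", "SU4", "SU5")`.
#' @export
default_desensitizable <- function() c("SU3", "SU4", "SU5")

check_subunits <- function(subunit) {
  bad <- setdiff(subunit, subunit_ids())
  if (length(bad)) {
    stop("unknown subunit label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(subunit)
}

#' Model variants
#'
#' Five Markov-scheme variants are supported:
#' \describe{
#'   \item{CONCERTED}{pseudo-symmetrical global states only: R, AR, AO plus a
#'     fast and a slow desensitized state branching off AO.}
#'   \item{I}{subunits desensitize independently; a single desensitized
#'     subunit occludes the pore (only AO conducts).}
#'   \item{II}{as I, but at least two desensitized subunits are needed to
#'     occlude the pore (AO and all singly-desensitized states conduct).}
#'   \item{II_BETA}{as II, plus a cross effect of the SU3 mutation on SU4's
#'     desensitization and recovery rates (multipliers c34+/c34-).}
#'   \item{III}{as II_BETA, plus wild-type inter-subunit couplings: mutual
#'     acceleration (gamma) of SU3/SU4 desensitization and mutual slowing
#'     (epsilon) of SU4/SU5 recovery.}
#' }
#'
#' @return Character vector of the variant names.
#' @export
model_variants <- function() c("CONCERTED", "I", "II", "II_BETA", "III")

check_variant <- function(variant) {
  match.arg(variant, model_variants())
}

pattern_label <- function(pattern) {
  if (length(pattern) == 0) return("AO")
  paste0("AD", paste(sub("^SU", "", sort(pattern)), collapse = ""))
}

#' Enumerate receptor states
#'
#' Builds the ordered state list of the non-concerted schemes: the resting
#' state `R`, the agonist-bound closed state `AR`, and one gated state per
#' subset of the desensitizable subunits (`AO` for the empty subset, `ADij...`
#' otherwise). For `n` desensitizable subunits this yields `2 + 2^n` states.
#' Canonical order: R, AR, then gated patterns by increasing number of
#' desensitized subunits and lexicographic subunit label, which makes every
#' downstream matrix reproducible across runs.
#'
#' @param desensitizable Character vector, subset of [subunit_ids()].
#'   Default `c("SU3","SU4","SU5")` (10 states); all five subunits give 34.
#' @param variant Optional model variant; if supplied, the `conducting` column
#'   is filled via [conductance_rule()], otherwise it is `NA`.
#' @return A data frame with one row per state: `label`, `tag` (`"R"`, `"AR"`
#'   or `"GATED"`), `pattern` (list column of desensitized-subunit sets),
#'   `n_desens` and `conducting`.
#' @examples
#' nrow(enumerate_states())                    # 10
#' nrow(enumerate_states(subunit_ids()))       # 34
#' nrow(enumerate_states(character()))         # 3: R, AR, AO
#' @export
enumerate_states <- function(desensitizable = default_desensitizable(),
                             variant = NULL) {
  check_subunits(desensitizable)
  desensitizable <- sort(unique(desensitizable))
  n <- length(desensitizable)
  patterns <- list(character())
  if (n > 0) {
    for (k in seq_len(n)) {
      combs <- utils::combn(desensitizable, k, simplify = FALSE)
      patterns <- c(patterns, combs)
    }
  }
  # combn() already emits each cardinality in lexicographic order
  states <- data.frame(
    label = c("R", "AR", vapply(patterns, pattern_label, character(1))),
    tag = c("R", "AR", rep("GATED", length(patterns))),
    stringsAsFactors = FALSE
  )
  states$pattern <- c(list(character()), list(character()), patterns)
  states$n_desens <- vapply(states$pattern, length, integer(1))
  states$n_desens[states$tag != "GATED"] <- NA_integer_
  states$conducting <- if (is.null(variant)) {
    NA
  } else {
    conductance_rule(states, variant)
  }
  attr(states, "desensitizable") <- desensitizable
  states
}

#' Conductance rule of a model variant
#'
#' `R` and `AR` never conduct. Under the CONCERTED and Model I rules only the
#' fully open gated state `AO` conducts (one desensitized subunit shuts the
#' pore). Under Models II, II-beta and III a gated state conducts as long as
#' at most one subunit is desensitized: two rearranged subunits are required
#' to occlude the pore.
#'
#' @param state A state data frame (or subset of rows) as returned by
#'   [enumerate_states()].
#' @param variant One of [model_variants()].
#' @return Logical vector, one entry per state row.
#' @export
conductance_rule <- function(state, variant) {
  variant <- check_variant(variant)
  gated <- state$tag == "GATED"
  nd <- vapply(state$pattern, length, integer(1))
  if (variant %in% c("CONCERTED", "I")) {
    gated & nd == 0L
  } else {
    gated & nd <= 1L
  }
}
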