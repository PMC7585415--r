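# State enumeration, conductance rules, effective rates, generator assembly.

test_that("state count is 2 + 2^n and the canonical order is stable", {
  s10 <- enumerate_states(c("SU3", "SU4", "SU5"))
  expect_equal(nrow(s10), 10)
  expect_equal(s10$label[1:3], c("R", "AR", "AO"))
  expect_equal(s10$label,
               c("R", "AR", "AO", "AD3", "AD4", "AD5", "AD34", "AD35",
                 "AD45", "AD345"))
  expect_equal(nrow(enumerate_states(subunit_ids())), 34)
  expect_equal(nrow(enumerate_states(character())), 3)
  for (n in 0:5) {
    expect_equal(nrow(enumerate_states(subunit_ids()[seq_len(n)])),
                 2 + 2^n)
  }
})

test_that("conductance rules follow the variant's pore-occlusion hypothesis", {
  s <- enumerate_states()
  lab <- function(v) s$label[conductance_rule(s, v)]
  expect_equal(lab("I"), "AO")
  expect_equal(lab("CONCERTED"), "AO")
  expect_setequal(lab("II"), c("AO", "AD3", "AD4", "AD5"))
  expect_setequal(lab("III"), c("AO", "AD3", "AD4", "AD5"))
  # AD4 is shut under Model I but conducting under Model II
  ad4 <- s[s$label == "AD4", ]
  expect_false(conductance_rule(ad4, "I"))
  expect_true(conductance_rule(ad4, "II"))
})

test_that("effective rates apply couplings, cross effects and multipliers", {
  p <- rate_parameters(gamma_coupling = 100, epsilon_coupling = 10)
  wt <- mutation_profile()
  # gamma: SU3 desensitizing while SU4 is desensitized
  expect_equal(effective_rate("AD4", "AD34", p, wt, "III"),
               100 * p$delta3_plus)
  # and reciprocally for SU4 while SU3 is desensitized
  expect_equal(effective_rate("AD3", "AD34", p, wt, "III"),
               100 * p$delta_plus)
  # epsilon: SU5 recovery slowed while SU4 is desensitized
  expect_equal(effective_rate("AD45", "AD4", p, wt, "III"),
               p$delta_minus / 10)
  expect_equal(effective_rate("AD45", "AD5", p, wt, "III"),
               p$delta_minus / 10)
  # no coupling between SU3 and SU5
  expect_equal(effective_rate("AD5", "AD35", p, wt, "III"), p$delta3_plus)
  # mutation multiplier on desensitization
  m4 <- mutation_profile("SU4", c4_plus = 7)
  expect_equal(effective_rate("AO", "AD4", p, m4, "II"), 7 * p$delta_plus)
  expect_equal(effective_rate("AO", "AD4", p, wt, "I"), p$delta_plus)
  # c34 cross effect needs SU3 mutated and Models II-beta/III
  m3 <- mutation_profile("SU3", c3_plus = 2, c34_plus = 5, c34_minus = 3)
  expect_equal(effective_rate("AO", "AD4", p, m3, "III"), 5 * p$delta_plus)
  expect_equal(effective_rate("AD4", "AO", p, m3, "III"), 3 * p$delta_minus)
  expect_equal(effective_rate("AO", "AD4", p, m3, "II"), p$delta_plus)
  # non-adjacent states error
  expect_error(effective_rate("AO", "AD34", p, wt, "III"), "not connected")
})

test_that("generator rows sum to zero for all variants and mutant profiles", {
  p <- rate_parameters(gamma_coupling = 100, epsilon_coupling = 10)
  subsets <- list(character(), "SU3", "SU4", "SU5", c("SU3", "SU4"),
                  c("SU3", "SU5"), c("SU4", "SU5"), c("SU3", "SU4", "SU5"))
  for (v in model_variants()) {
    for (mut in subsets) {
      args <- list(mutated = mut)
      for (su in mut) {
        i <- sub("SU", "", su)
        args[[paste0("c", i, "_plus")]] <- 4
      }
      if ("SU3" %in% mut && v %in% c("II_BETA", "III")) {
        args$c34_plus <- 2.5
      }
      if (v == "CONCERTED" && length(mut)) {
        args$concerted_factors <- stats::setNames(
          rep(list(c(2, 1.5, 3, 1.2)), length(mut)), mut)
      }
      prof <- do.call(mutation_profile, args)
      sch <- build_scheme(v, p, prof)
      expect_lt(max(abs(rowSums(sch$generator))),
                1e-9 * max(abs(sch$generator)))
      expect_true(all(sch$generator - diag(diag(sch$generator)) >= 0))
    }
  }
})

test_that("Model II equals Model III with unit couplings, entrywise", {
  p1 <- rate_parameters()  # gamma = epsilon = 1
  s2 <- build_scheme("II", p1)
  s3 <- build_scheme("III", p1)
  expect_equal(s2$generator, s3$generator)
})

test_that("unit multipliers reproduce the wild-type generator", {
  p <- rate_parameters(gamma_coupling = 10, epsilon_coupling = 5)
  wt <- build_scheme("III", p)
  m <- build_scheme("III", p, mutation_profile(c("SU3", "SU4", "SU5")))
  expect_equal(wt$generator, m$generator)
})

test_that("Model I wild type has exactly one conducting state", {
  sch <- build_scheme("I", rate_parameters())
  expect_equal(sum(sch$conducting), 1)
  expect_equal(sch$states$label[sch$conducting], "AO")
})

test_that("SU4/SU5 mutation swap leaves the Model I/II spectrum unchanged", {
  p <- rate_parameters()
  for (v in c("I", "II")) {
    a <- build_scheme(v, p, mutation_profile("SU4", c4_plus = 9,
                                             c4_minus = 3))
    b <- build_scheme(v, p, mutation_profile("SU5", c5_plus = 9,
                                             c5_minus = 3))
    ev_a <- sort(Re(eigen(a$generator, only.values = TRUE)$values))
    ev_b <- sort(Re(eigen(b$generator, only.values = TRUE)$values))
    expect_equal(ev_a, ev_b, tolerance = 1e-9)
  }
})

test_that("desensitization 4-cycles satisfy detailed balance; a perturbed
           rate is detected", {
  p <- rate_parameters(gamma_coupling = 100, epsilon_coupling = 10)
  for (v in c("I", "II", "II_BETA", "III")) {
    prof <- mutation_profile("SU3", c3_plus = 6, c3_minus = 2,
                             c34_plus = 3, c34_minus = 2)
    sch <- build_scheme(v, p, prof)
    rep <- check_detailed_balance(sch)
    expect_equal(attr(rep, "n_violations"), 0)
  }
  sch <- build_scheme("III", p)
  sch$generator["AO", "AD4"] <- sch$generator["AO", "AD4"] * 1.5
  rep <- check_detailed_balance(sch)
  expect_gt(attr(rep, "n_violations"), 0)
  expect_true(any(rep$violated & rep$base == "AO"))
})

test_that("dimensional sanity: binding flux scales with concentration", {
  p <- rate_parameters()
  s1 <- build_scheme("I", p, agonist_conc = 0.01)
  s2 <- build_scheme("I", p, agonist_conc = 0.001)
  expect_equal(s1$generator["R", "AR"], p$k_on * 0.01)
  expect_equal(s1$generator["R", "AR"] / s2$generator["R", "AR"], 10)
})

test_that("scheme edge list and model config round-trip", {
  p <- rate_parameters(delta_plus = 0.33, gamma_coupling = 100,
                       epsilon_coupling = 10)
  prof <- mutation_profile(c("SU3", "SU4", "SU5"), c3_plus = 2,
                           c4_plus = 5, c5_plus = 5, c34_plus = 3)
  sch <- build_scheme("III", p, prof, agonist_conc = 0.01)
  edges <- scheme_edges(sch)
  expect_true(all(c("from", "to", "rate", "descriptor") %in% names(edges)))
  expect_equal(nrow(edges), nrow(sch$transitions))
  path <- tempfile(fileext = ".yaml")
  write_model_config("III", p, prof, 0.01, path)
  back <- read_model_config(path)
  expect_equal(back$variant, "III")
  expect_equal(back$params, p)
  expect_equal(back$profile, prof)
  sch2 <- build_scheme(back$variant, back$params, back$profile,
                       back$agonist_conc)
  expect_equal(sch$generator, sch2$generator)
})
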