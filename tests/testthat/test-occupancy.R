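# Occupancy time courses and the kinetically favored pathway.

test_that("occupancies stay normalized and desensitized states stay empty
           when desensitization is off", {
  p <- rate_parameters(delta_plus = 1e-12, delta_minus = 1,
                       delta3_plus = 1e-12, delta3_minus = 1)
  sch <- build_scheme("III", p)
  oc <- occupancy_timecourses(sch, agonist_protocol(durations = 10))
  traj <- attr(oc, "trajectory")
  expect_lt(max(abs(rowSums(traj$probabilities) - 1)), 1e-8)
  for (g in c("AD3", "AD4", "AD5", "AD34", "AD35", "AD45", "AD345")) {
    expect_lt(max(oc[[g]]), 1e-9)
  }
})

test_that("with only SU3 desensitizing the pathway is AO -> AD3", {
  p <- rate_parameters()
  sch <- build_scheme("I", p, desensitizable = "SU3")
  pw <- dominant_pathway(sch, agonist_protocol(durations = 30))
  expect_equal(pw$path, c("AO", "AD3"))
})

test_that("symmetric SU4/SU5 rates give a co-dominant first step", {
  p <- rate_parameters()
  sch <- build_scheme("II", p, desensitizable = c("SU4", "SU5"))
  pw <- dominant_pathway(sch, agonist_protocol(durations = 30))
  expect_equal(pw$path[1:2], c("AO", "AD4"))  # canonical tie-break
  expect_equal(pw$edges$co_dominant[1], "AD5")  # but reported as tied
})

test_that("net flux into the terminal state matches its final occupancy", {
  fit <- wt_fit("III", gamma = 100, epsilon = 10)
  sch <- build_scheme("III", fit$params)
  prot <- agonist_protocol(durations = 60, dt = 0.002)
  traj <- propagate(sch, prot)
  w <- gabadesens:::trapezoid_weights(traj$times)
  term <- "AD345"
  tbl <- sch$transitions
  net <- 0
  for (k in seq_len(nrow(tbl))) {
    if (tbl$to[k] == term) {
      net <- net + tbl$rate[k] * sum(w * traj$probabilities[, tbl$from[k]])
    }
    if (tbl$from[k] == term) {
      net <- net - tbl$rate[k] * sum(w * traj$probabilities[, term])
    }
  }
  final <- traj$probabilities[nrow(traj$probabilities), term]
  expect_equal(net, final, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("calibrated wild type: AD45 dominates the early phase, AD345 the
           late phase, and the pathway runs AO -> AD4/AD5 -> AD45 -> AD345", {
  fit <- wt_fit("III", gamma = 100, epsilon = 10)
  sch <- build_scheme("III", fit$params)
  oc <- occupancy_timecourses(sch, agonist_protocol(durations = 60))
  early <- oc[oc$time <= 10, ]
  # the early desensitization is carried by AD45, not the other doubly
  # desensitized states
  expect_gt(max(early$AD45), max(early$AD34))
  expect_gt(max(early$AD45), max(early$AD35))
  late <- oc[nrow(oc), ]
  des_states <- c("AD3", "AD4", "AD5", "AD34", "AD35", "AD45", "AD345")
  expect_equal(des_states[which.max(unlist(late[des_states]))], "AD345")
  pw <- dominant_pathway(sch, traj = attr(oc, "trajectory"))
  expect_equal(pw$path, c("AO", "AD4", "AD45", "AD345"))
  expect_equal(pw$edges$co_dominant[1], "AD5")
})
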