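test_that("initial distribution encodes the responder split", {
  p <- base_params()
  expect_equal(build_initial_distribution(p$arms[[1]]),
               c(improved = 0.6012458, unimproved = 0.3987542, dead = 0))
  expect_equal(build_initial_distribution(0.5),
               c(improved = 0.5, unimproved = 0.5, dead = 0))
  expect_equal(unname(build_initial_distribution(0.4302036)[1]), 0.4302036)
  expect_error(build_initial_distribution(1.2))
})

test_that("a single transition applies mortality then relapse", {
  expect_equal(markov_step(c(1, 0, 0), 0.0124, 0),
               c(improved = 0.9876, unimproved = 0.0124, dead = 0))
  # no unimproved -> improved flow in the base case
  expect_equal(markov_step(c(0, 1, 0), 0.5, 0),
               c(improved = 0, unimproved = 1, dead = 0))
  expect_equal(markov_step(c(0.5, 0.5, 0), 0, 0.0010),
               c(improved = 0.4995, unimproved = 0.4995, dead = 0.0010))
  # unimproved mortality multiplier scales only the unimproved flow to death
  out <- markov_step(c(0.5, 0.5, 0), 0, 0.001, unimproved_mortality_multiplier = 2)
  expect_equal(unname(out), c(0.4995, 0.4990, 0.0015))
  expect_error(markov_step(c(0.7, 0.7, 0), 0.1, 0.1))
})

test_that("discount factors follow the timing convention", {
  s0 <- cic_settings(annual_discount_rate = 0)
  expect_identical(discount_factor(0:25, s0), rep(1, 26))
  s_start <- cic_settings(discount_timing = "cycle-start")
  expect_identical(discount_factor(0, s_start), 1)
  # 1.02^(-13 * 28 / 365), frozen from exp(-(364/365) * log(1.02))
  expect_equal(discount_factor(13, s_start), 0.9804453483, tolerance = 1e-9)
  s_end <- cic_settings(discount_timing = "cycle-end")
  expect_equal(discount_factor(12, s_end), discount_factor(13, s_start))
  expect_lt(discount_factor(0, s_end), 1)
})

test_that("a stationary cohort accrues the improved-state payoffs exactly", {
  p <- modify_params(base_params(),
                     settings = list(annual_discount_rate = 0),
                     transitions = list(annual_relapse_prob = 0,
                                        annual_mortality_prob = 0))
  arm <- cic_arm("stay", drug_cost_per_cycle = 4715.2,
                 responder_proportion = 1 - 1e-12)
  res <- run_cohort(arm, p)$result
  expect_equal(res$total_cost,
               26 * (4715.2 + p$costs$caregiving_improved_per_cycle +
                       p$costs$productivity_improved_per_cycle),
               tolerance = 1e-9)
  expect_equal(res$qol_score, 1.64, tolerance = 1e-9)
  expect_equal(res$improved_duration, 26, tolerance = 1e-9)
})

test_that("occupancy is conserved and death is monotone for every arm", {
  p <- base_params()
  for (arm in p$arms) {
    cr <- run_cohort(arm, p)
    expect_true(all(abs(rowSums(cr$trace) - 1) < 1e-12))
    expect_true(all(abs(rowSums(cr$eff) - 1) < 1e-12))
    expect_true(all(diff(cr$trace[, "dead"]) >= 0))
    # no unimproved -> improved flow: improved occupancy never increases
    expect_true(all(diff(cr$trace[, "improved"]) <= 1e-15))
    expect_true(all(cr$trace >= 0))
  }
})

test_that("conservation holds on jittered parameter sets", {
  for (seed in 1:5) {
    p <- generate_parameter_set(base_params(), jitter = 0.3, seed = seed)
    cr <- run_cohort(p$arms[[2]], p)
    expect_true(all(abs(rowSums(cr$trace) - 1) < 1e-12))
    expect_true(all(diff(cr$trace[, "dead"]) >= 0))
  }
})

test_that("improved duration matches its geometric-series closed form", {
  for (conv in c("mortality-first", "accrue-first")) {
    p <- base_case_params(cycle_convention = conv)
    m <- p$transitions$cycle_mortality_prob
    r <- p$transitions$cycle_relapse_prob
    surv <- (1 - m) * (1 - r)
    for (arm in p$arms) {
      closed <- arm$responder_proportion * sum(surv^(0:25)) *
        (if (conv == "mortality-first") 1 - m else 1)
      expect_equal(run_cohort(arm, p)$result$improved_duration, closed,
                   tolerance = 1e-9)
    }
  }
})

test_that("undiscounted QoL equals the person-cycle weighted closed form", {
  p <- base_case_params(annual_discount_rate = 0)
  cr <- run_cohort(p$arms[[1]], p)
  by_hand <- (1.64 * sum(cr$eff[, "improved"]) +
                1.88 * sum(cr$eff[, "unimproved"])) / 26
  expect_equal(cr$result$qol_score, by_hand, tolerance = 1e-12)
  expect_equal(sum(cr$eff[, "improved"]), cr$result$improved_duration,
               tolerance = 1e-12)
})

test_that("comparisons are zero against self and independent of arm order", {
  p <- base_params()
  res <- run_base_case(p)
  ref <- arm_row(res, p$reference_arm)
  expect_identical(ref$d_total_cost, 0)
  expect_identical(ref$d_qol, 0)
  expect_identical(ref$d_duration, 0)
  expect_error(compare_arms(res, "nonexistent"), "not in results")

  p_rev <- p
  p_rev$arms <- rev(p$arms)
  res_rev <- run_base_case(p_rev)
  for (a in res$arm) {
    expect_identical(arm_row(res_rev, a)[, 1:9], arm_row(res, a)[, 1:9])
  }
})

test_that("total cost is the exact sum of its components", {
  res <- run_arms(base_params())
  expect_identical(res$total_cost,
                   res$medical_cost + res$caregiving_cost + res$productivity_cost)
  expect_true(all(res$qol_score <= base_params()$qol$unimproved_score))
  expect_true(all(res$improved_duration >= 0 & res$improved_duration <= 26))
})

test_that("the microsimulation reproduces the cohort model within Monte-Carlo error", {
  p <- base_params()
  cr <- run_cohort(p$arms[[1]], p)$result
  ms <- microsim_oracle(p$arms[[1]], p, n_patients = 50000, seed = 4)
  expect_lt(abs(ms$total_cost - cr$total_cost), 3 * ms$se_total_cost)
  expect_lt(abs(ms$qol_score - cr$qol_score), 3 * ms$se_qol)
  expect_lt(abs(ms$improved_duration - cr$improved_duration), 3 * ms$se_duration)
})
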