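test_that("zero-width perturbation bounds are rejected and groups cover the published rows", {
  p <- base_params()
  expect_error(run_dsa(p, perturbation = 0))
  g <- dsa_groups(p)
  # efficacy x3, qol, medical, drug cost x3, productivity, caregiving
  expect_length(g, 10)
  expect_true(all(c("qol", "medical_cost", "productivity_loss",
                    "caregiving_cost") %in% names(g)))
  expect_gt(length(dsa_groups(p, per_scalar = TRUE)), 10)
})

test_that("DSA perturbations leave all other arms and groups at base case", {
  p <- base_params()
  base <- run_base_case(p)
  dsa <- run_dsa(p, 0.2)
  # perturbing linaclotide's efficacy must not move elobixibat or lubiprostone
  sub <- dsa[dsa$group == "efficacy_linaclotide_0.5mg", ]
  for (a in c("elobixibat_10mg", "lubiprostone_48ug")) {
    expect_equal(arm_row(sub[sub$direction == "lower", ], a)$total_cost,
                 arm_row(base, a)$total_cost)
  }
})

test_that("DSA is symmetric about base case for linear cost parameters", {
  p <- base_params()
  base <- run_base_case(p)
  dsa <- run_dsa(p, 0.2)
  for (g in c("drug_cost_elobixibat_10mg", "medical_cost",
              "productivity_loss", "caregiving_cost")) {
    sub <- dsa[dsa$group == g, ]
    for (a in base$arm) {
      lo <- arm_row(sub[sub$direction == "lower", ], a)$total_cost
      hi <- arm_row(sub[sub$direction == "upper", ], a)$total_cost
      b <- arm_row(base, a)$total_cost
      expect_equal(hi - b, b - lo, tolerance = 1e-9)
      # qol untouched by pure cost perturbations
      expect_equal(arm_row(sub[sub$direction == "lower", ], a)$qol_score,
                   arm_row(base, a)$qol_score)
    }
  }
})

test_that("a pure cost perturbation moves total cost by exactly its share", {
  p <- base_params()
  base <- run_base_case(p)
  dsa <- run_dsa(p, 0.2)
  # drug-cost contribution of the reference arm = drug price x discounted
  # alive person-cycles; +/-20% moves total by exactly 20% of it
  lo <- arm_row(dsa[dsa$group == "drug_cost_elobixibat_10mg" &
                      dsa$direction == "lower", ], "elobixibat_10mg")$total_cost
  cr <- run_cohort(base_params()$arms[[1]], p)
  disc <- discount_factor(0:25, p$settings)
  drug_contrib <- 4715.2 * sum(disc * (cr$eff[, "improved"] + cr$eff[, "unimproved"]))
  expect_equal(arm_row(base, "elobixibat_10mg")$total_cost - lo,
               0.2 * drug_contrib, tolerance = 1e-9)
})

test_that("QoL perturbation scales the score linearly and exactly", {
  p <- base_params()
  base <- run_base_case(p)
  dsa <- run_dsa(p, 0.2)
  sub <- dsa[dsa$group == "qol", ]
  for (a in base$arm) {
    expect_equal(arm_row(sub[sub$direction == "lower", ], a)$qol_score,
                 0.8 * arm_row(base, a)$qol_score, tolerance = 1e-12)
    expect_equal(arm_row(sub[sub$direction == "upper", ], a)$qol_score,
                 1.2 * arm_row(base, a)$qol_score, tolerance = 1e-12)
    expect_equal(arm_row(sub[sub$direction == "lower", ], a)$total_cost,
                 arm_row(base, a)$total_cost)
  }
})

test_that("probabilities perturbed above one are clamped with a warning", {
  p <- base_params()
  g <- dsa_groups(p)
  p_hi <- modify_params(p) # copy
  i <- match("elobixibat_10mg", vapply(p_hi$arms, `[[`, "", "name"))
  p_hi$arms[[i]]$responder_proportion <- 0.95
  expect_warning(g[["efficacy_elobixibat_10mg"]](p_hi, 1.2), "clamped")
})

test_that("PSA is reproducible under a seed and order-invariant in its summaries", {
  p <- base_params()
  a <- run_psa(p, n_draws = 200, seed = 7)
  b <- run_psa(p, n_draws = 200, seed = 7)
  expect_identical(a$samples, b$samples)
  expect_identical(a$summary, b$summary)
  # summary recomputed from shuffled samples is unchanged
  shuffled <- a$samples[sample(nrow(a$samples)), ]
  shuffled <- shuffled[order(match(shuffled$arm, unique(a$samples$arm)),
                             shuffled$draw), ]
  expect_equal(ce_plane_summary(shuffled, "linaclotide_0.5mg",
                                reference = "elobixibat_10mg"),
               a$summary[a$summary$comparison == "linaclotide_0.5mg", ])
})

test_that("degenerate PSA distributions recover the base case on every draw", {
  p <- base_params()
  dists <- default_psa_distributions(p)
  dists <- lapply(dists, function(d) { d$sd <- 0; d })
  psa <- run_psa(p, n_draws = 5, seed = 1, distributions = dists)
  base <- run_arms(p)
  for (a in base$arm) {
    draws <- psa$samples[psa$samples$arm == a, ]
    expect_equal(draws$total_cost, rep(arm_row(base, a)$total_cost, 5),
                 tolerance = 1e-9)
    expect_equal(draws$qol_score, rep(arm_row(base, a)$qol_score, 5),
                 tolerance = 1e-9)
  }
  expect_true(all(psa$summary$ref_better_qol %in% c(0, 1)))
})

test_that("cost-effectiveness-plane proportions are coherent", {
  psa <- run_psa(base_params(), n_draws = 400, seed = 13)
  s <- psa$summary
  expect_true(all(s$ref_better_qol >= 0 & s$ref_better_qol <= 1))
  expect_true(all(s$ref_lower_cost >= 0 & s$ref_lower_cost <= 1))
  expect_true(all(s$ref_better_both <= pmin(s$ref_better_qol, s$ref_lower_cost)))
  expect_true(all(s$d_cost_lo <= s$d_cost_hi))
  expect_true(all(s$d_qol_lo <= s$d_qol_hi))
  expect_error(ce_plane_summary(psa$samples[0, ], "linaclotide_0.5mg",
                                reference = "elobixibat_10mg"), "empty")
})

test_that("credible intervals contain the base-case deltas under the shipped distributions", {
  psa <- run_psa(base_params(), n_draws = 500, seed = 21)
  base <- run_base_case(base_params())
  for (cmp in psa$summary$comparison) {
    s <- psa$summary[psa$summary$comparison == cmp, ]
    d <- arm_row(base, cmp)
    expect_gt(d$d_total_cost, s$d_cost_lo)
    expect_lt(d$d_total_cost, s$d_cost_hi)
    expect_gt(d$d_qol, s$d_qol_lo)
    expect_lt(d$d_qol, s$d_qol_hi)
  }
})
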