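#' Generate synthesized SBM summaries from a known truth
#'
#' Emulates the evidence base the responder estimator consumes: for each arm,
#' simulates `n_studies` trials of `n_per_study` patients whose weekly SBM
#' outcomes are normal with the arm's true mean and SD, then pools them by
#' inverse-variance (fixed effect) into a synthesized mean and a pooled SD.
#' Because the truth is known, recovery can be tested.
#'
#' @param truth Data frame with columns `arm`, `mean_sbm`, `sd_sbm`, and
#'   optionally `n_studies` (default 3) and `n_per_study` (default 100).
#' @param seed Integer seed.
#' @return Tibble with columns `arm`, `mean_sbm`, `sd_sbm`, `n_total`,
#'   suitable for [responder_proportions()].
#' @export
generate_sbm_summaries <- function(truth, seed = 1L) {
  stopifnot(all(c("arm", "mean_sbm", "sd_sbm") %in% names(truth)),
            all(truth$sd_sbm >= 0))
  n_studies <- truth$n_studies %||% rep(3L, nrow(truth))
  n_per <- truth$n_per_study %||% rep(100L, nrow(truth))
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      means <- numeric(n_studies[i])
      vars <- numeric(n_studies[i])
      for (j in seq_len(n_studies[i])) {
        x <- stats::rnorm(n_per[i], truth$mean_sbm[i], truth$sd_sbm[i])
        means[j] <- mean(x)
        vars[j] <- if (truth$sd_sbm[i] == 0) 0 else stats::var(x)
      }
      if (all(vars == 0)) {
        pooled_mean <- mean(means)
        pooled_sd <- 0
      } else {
        w <- n_per[i] / vars
        pooled_mean <- sum(w * means) / sum(w)
        pooled_sd <- sqrt(sum((n_per[i] - 1) * vars) /
                            (n_studies[i] * (n_per[i] - 1)))
      }
      tibble::tibble(arm = truth$arm[i], mean_sbm = pooled_mean,
                     sd_sbm = pooled_sd, n_total = n_studies[i] * n_per[i])
    })
    do.call(rbind, rows)
  })
}

#' Jitter a parameter set
#'
#' Independently perturbs each scalar input by a multiplicative uniform
#' factor in `[1 - jitter, 1 + jitter]`, respecting type invariants
#' (probabilities stay inside (0, 1), costs stay non-negative, the unimproved
#' PAC-QoL score stays at least the improved score). Derived per-cycle
#' quantities are recomputed from the perturbed inputs. Used to exercise the
#' DSA/PSA machinery on parameter sets other than the base case.
#'
#' @param base A `cic_params` object.
#' @param jitter Relative perturbation bound in `[0, 1)`.
#' @param seed Integer seed.
#' @return A validated, perturbed `cic_params` object.
#' @export
generate_parameter_set <- function(base, jitter, seed = 1L) {
  stopifnot(jitter >= 0, jitter < 1)
  with_seed(seed, {
    jf <- function(x) x * stats::runif(length(x), 1 - jitter, 1 + jitter)
    jp <- function(x) pmin(pmax(jf(x), 1e-9), 1 - 1e-9)
    p <- base
    p$arms <- lapply(p$arms, function(a) {
      a$responder_proportion <- jp(a$responder_proportion)
      a$drug_cost_per_cycle <- jf(a$drug_cost_per_cycle)
      a
    })
    tr <- p$transitions
    tr$annual_relapse_prob <- jp(tr$annual_relapse_prob)
    tr$annual_mortality_prob <- jp(tr$annual_mortality_prob)
    p$transitions <- tr
    p$qol$improved_score <- min(jf(p$qol$improved_score), 4)
    p$qol$unimproved_score <- min(max(jf(p$qol$unimproved_score),
                                      p$qol$improved_score), 4)
    for (fld in c("disimpaction_per_cycle", "enema_per_cycle",
                  "addon_stimulant_per_cycle", "addon_osmotic_per_cycle")) {
      p$costs[[fld]] <- jf(p$costs[[fld]])
    }
    cc <- p$cost_components
    cc$prop_age_ge65 <- jp(cc$prop_age_ge65)
    cc$prop_needing_care <- jp(cc$prop_needing_care)
    cc$avg_wage_per_cycle <- jf(cc$avg_wage_per_cycle)
    cc$care_time_frac_improved <- jp(cc$care_time_frac_improved)
    cc$care_time_frac_unimproved <- max(jp(cc$care_time_frac_unimproved),
                                        cc$care_time_frac_improved)
    cc$impairment_improved <- jp(cc$impairment_improved)
    cc$impairment_unimproved <- max(jp(cc$impairment_unimproved),
                                    cc$impairment_improved)
    p$cost_components <- cc
    p <- derive_params(p)
    validate_params(p)
    p
  })
}

#' Individual-level microsimulation oracle
#'
#' Brute-force estimator of the cohort expectations: simulates `n_patients`
#' independent patients through the same per-cycle probabilities and accrual
#' convention as [run_cohort()], with Bernoulli death and relapse draws per
#' patient per cycle, and averages the discounted payoffs. Converges to the
#' cohort-model values at rate 1/sqrt(n); the returned standard errors allow
#' a 3-SE agreement check. Supports the memoryless model only (the add-on
#' tunnel extension is out of its scope).
#'
#' @param arm A [cic_arm()] object or arm name.
#' @param params A `cic_params` object with `addon$enabled = FALSE`.
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed.
#' @return One-row tibble with the [run_cohort()] result columns plus
#'   Monte-Carlo standard errors (`se_total_cost`, `se_qol`, `se_duration`).
#' @export
microsim_oracle <- function(arm, params, n_patients, seed = 1L) {
  stopifnot(n_patients >= 1)
  validate_params(params)
  if (isTRUE(params$addon$enabled)) {
    stop("microsim_oracle supports the memoryless model only", call. = FALSE)
  }
  if (is.character(arm)) {
    nm <- vapply(params$arms, `[[`, "", "name")
    arm <- params$arms[[match(arm, nm)]]
  }
  s <- params$settings
  tr <- params$transitions
  co <- params$costs
  mortality_first <- s$cycle_convention == "mortality-first"
  disc <- discount_factor(seq_len(s$n_cycles) - 1, s)
  pay_med <- c(arm$drug_cost_per_cycle,
               arm$drug_cost_per_cycle + co$disimpaction_per_cycle + co$enema_per_cycle)
  pay_cg <- c(co$caregiving_improved_per_cycle, co$caregiving_unimproved_per_cycle)
  pay_pr <- c(co$productivity_improved_per_cycle, co$productivity_unimproved_per_cycle)
  pay_q <- c(params$qol$improved_score, params$qol$unimproved_score)
  with_seed(seed, {
    n <- n_patients
    # state per patient: 1 improved, 2 unimproved, 0 dead
    state <- ifelse(stats::runif(n) < arm$responder_proportion, 1L, 2L)
    med <- cg <- pr <- qs <- dur <- numeric(n)
    for (t in seq_len(s$n_cycles)) {
      if (mortality_first) {
        alive <- state > 0L
        pm <- ifelse(state == 2L, tr$cycle_mortality_prob * tr$unimproved_mortality_multiplier,
                     tr$cycle_mortality_prob)
        dies <- alive & (stats::runif(n) < pm)
        state[dies] <- 0L
      }
      imp <- state == 1L
      uni <- state == 2L
      df <- disc[t]
      med[imp] <- med[imp] + df * pay_med[1]; med[uni] <- med[uni] + df * pay_med[2]
      cg[imp] <- cg[imp] + df * pay_cg[1]; cg[uni] <- cg[uni] + df * pay_cg[2]
      pr[imp] <- pr[imp] + df * pay_pr[1]; pr[uni] <- pr[uni] + df * pay_pr[2]
      qs[imp] <- qs[imp] + df * pay_q[1]; qs[uni] <- qs[uni] + df * pay_q[2]
      dur[imp] <- dur[imp] + 1
      if (!mortality_first) {
        alive <- state > 0L
        pm <- ifelse(state == 2L, tr$cycle_mortality_prob * tr$unimproved_mortality_multiplier,
                     tr$cycle_mortality_prob)
        dies <- alive & (stats::runif(n) < pm)
        state[dies] <- 0L
      }
      relapses <- state == 1L & (stats::runif(n) < tr$cycle_relapse_prob)
      state[relapses] <- 2L
    }
    total <- med + cg + pr
    se <- function(x) stats::sd(x) / sqrt(n)
    tibble::tibble(
      arm = arm$name,
      medical_cost = mean(med), caregiving_cost = mean(cg),
      productivity_cost = mean(pr), total_cost = mean(total),
      qol_score = mean(qs) / s$n_cycles, improved_duration = mean(dur),
      se_total_cost = se(total), se_qol = se(qs) / s$n_cycles,
      se_duration = se(dur), n_patients = n
    )
  })
}
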