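#' Initial state distribution after the responder split
#'
#' The transient entry state (untreated chronic constipation) is resolved at
#' time zero: responders (>= 3 SBMs/week) start the first cycle improved, the
#' rest unimproved, nobody dead.
#'
#' @param arm A [cic_arm()] object, or a bare responder proportion.
#' @return Named numeric vector `c(improved, unimproved, dead)`.
#' @export
build_initial_distribution <- function(arm) {
  p <- if (inherits(arm, "cic_arm")) arm$responder_proportion else arm
  stopifnot(p > 0, p < 1)
  c(improved = p, unimproved = 1 - p, dead = 0)
}

#' One Markov transition
#'
#' Applies, in order, background mortality (multiplied by
#' `unimproved_mortality_multiplier` in the unimproved state) and then the
#' improved-to-unimproved relapse; an optional unimproved-to-improved
#' improvement flow (used by the add-on scenario) is applied with the relapse.
#'
#' @param state Numeric vector `c(improved, unimproved, dead)` summing to 1.
#' @param cycle_relapse_prob Per-cycle relapse probability.
#' @param cycle_mortality_prob Per-cycle mortality probability.
#' @param unimproved_mortality_multiplier Mortality multiplier for the
#'   unimproved state (1 in the base case).
#' @param improvement_prob Per-cycle unimproved-to-improved probability
#'   (0 in the base case).
#' @return The next cycle's state distribution.
#' @export
markov_step <- function(state, cycle_relapse_prob, cycle_mortality_prob,
                        unimproved_mortality_multiplier = 1,
                        improvement_prob = 0) {
  stopifnot(length(state) == 3, abs(sum(state) - 1) < 1e-9, all(state >= -1e-12))
  m <- cycle_mortality_prob
  im <- state[[1]] * (1 - m)
  um <- state[[2]] * (1 - m * unimproved_mortality_multiplier)
  i2 <- im * (1 - cycle_relapse_prob) + um * improvement_prob
  u2 <- um * (1 - improvement_prob) + im * cycle_relapse_prob
  c(improved = i2, unimproved = u2, dead = 1 - i2 - u2)
}

#' Discount factor for one cycle
#'
#' Annual compounding over the elapsed model time. Under the default
#' `"cycle-end"` timing, cycle `t`'s accrual (0-based) is discounted by
#' `(t + 1)` cycle lengths; under `"cycle-start"`, by `t`.
#'
#' @param cycle_index 0-based cycle index.
#' @param settings A [cic_settings()] object.
#' @return Discount factor in (0, 1].
#' @export
discount_factor <- function(cycle_index, settings) {
  stopifnot(all(cycle_index >= 0))
  dt <- if (settings$discount_timing == "cycle-end") 1 else 0
  yrs <- (cycle_index + dt) * settings$cycle_length_days / settings$days_per_year
  (1 + settings$annual_discount_rate)^(-yrs)
}

# Lean scalar engine shared by run_cohort, the DSA and the PSA.
#
# `pars` fields: relapse, mort, mult, improvement, n_cycles, disc (vector of
# length n_cycles), mortality_first (logical), qol_i, qol_u, proc, cg_i, cg_u,
# pr_i, pr_u, n_stages (1 = memoryless), stim, osm.
# Returns the accumulated sums plus the start-of-cycle and accrual traces.
cohort_engine <- function(p_resp, drug_cost, pars) {
  n <- pars$n_cycles
  k <- pars$n_stages %||% 1L
  improvement <- pars$improvement %||% 0
  I <- p_resp
  U <- c(1 - p_resp, numeric(k - 1))
  trace <- matrix(0, n, 3, dimnames = list(NULL, c("improved", "unimproved", "dead")))
  eff <- trace
  med <- care <- prod <- qsum <- dur <- stim <- osm <- 0
  for (t in seq_len(n)) {
    trace[t, ] <- c(I, sum(U), 1 - I - sum(U))
    if (pars$mortality_first) {
      Ie <- I * (1 - pars$mort)
      Ue <- U * (1 - pars$mort * pars$mult)
    } else {
      Ie <- I
      Ue <- U
    }
    Ut <- sum(Ue)
    eff[t, ] <- c(Ie, Ut, 1 - Ie - Ut)
    df <- pars$disc[t]
    med <- med + df * (drug_cost * (Ie + Ut) + pars$proc * Ut)
    care <- care + df * (pars$cg_i * Ie + pars$cg_u * Ut)
    prod <- prod + df * (pars$pr_i * Ie + pars$pr_u * Ut)
    qsum <- qsum + df * (pars$qol_i * Ie + pars$qol_u * Ut)
    dur <- dur + Ie
    if (k > 1) {
      stim <- stim + df * pars$stim * Ue[k]
      osm <- osm + df * pars$osm * Ue[k]
    }
    if (!pars$mortality_first) {
      Ie <- Ie * (1 - pars$mort)
      Ue <- Ue * (1 - pars$mort * pars$mult)
    }
    newU <- numeric(k)
    newU[1] <- Ie * pars$relapse
    if (k > 1) {
      for (j in 2:k) newU[j] <- Ue[j - 1]
      newU[k] <- newU[k] + Ue[k] * (1 - improvement)
      I <- Ie * (1 - pars$relapse) + Ue[k] * improvement
    } else {
      newU[1] <- newU[1] + Ue[1] * (1 - improvement)
      I <- Ie * (1 - pars$relapse) + Ue[1] * improvement
    }
    U <- newU
    if (I < -1e-12 || any(U < -1e-12)) stop("negative occupancy", call. = FALSE)
  }
  list(
    trace = trace, eff = eff,
    sums = c(medical = med, caregiving = care, productivity = prod,
             qol = qsum, duration = dur, stimulant = stim, osmotic = osm)
  )
}

# Translate a cic_params object into the lean engine's parameter list.
engine_pars <- function(params) {
  s <- params$settings
  tr <- params$transitions
  co <- params$costs
  addon_on <- isTRUE(params$addon$enabled)
  improvement <- 0
  if (addon_on) {
    improvement <- params$addon$improvement_prob
    if (identical(params$addon$improvement_time_unit, "year")) {
      improvement <- annual_prob_to_cycle(improvement, s$cycle_length_days,
                                          s$days_per_year)
    }
  }
  list(
    relapse = tr$cycle_relapse_prob, mort = tr$cycle_mortality_prob,
    mult = tr$unimproved_mortality_multiplier,
    improvement = improvement,
    n_cycles = s$n_cycles,
    disc = discount_factor(seq_len(s$n_cycles) - 1, s),
    mortality_first = s$cycle_convention == "mortality-first",
    qol_i = params$qol$improved_score, qol_u = params$qol$unimproved_score,
    proc = co$disimpaction_per_cycle + co$enema_per_cycle,
    cg_i = co$caregiving_improved_per_cycle, cg_u = co$caregiving_unimproved_per_cycle,
    pr_i = co$productivity_improved_per_cycle, pr_u = co$productivity_unimproved_per_cycle,
    n_stages = if (addon_on) as.integer(params$addon$cycles_before_addon) else 1L,
    stim = co$addon_stimulant_per_cycle, osm = co$addon_osmotic_per_cycle
  )
}

#' Run the cohort model for one treatment arm
#'
#' Simulates the cohort over the horizon and accumulates discounted cost
#' components (medical = drug + bowel-management procedures, caregiving,
#' productivity), the discounted per-cycle PAC-QoL score (accumulated and
#' divided by the number of cycles; dead occupants contribute nothing while
#' the divisor stays fixed), and the undiscounted mean time spent improved.
#' When the add-on block is enabled the unimproved state is expanded into
#' tunnel stages so that occupants unimproved for `cycles_before_addon`
#' cycles accrue add-on drug costs and may transition back to improved.
#'
#' @param arm A [cic_arm()] object (or its name if `params` carries it).
#' @param params A `cic_params` object.
#' @return A `cic_arm_result`: list with `arm`, `trace` (start-of-cycle
#'   occupancy, rows summing to 1), `eff` (accrual-basis occupancy) and
#'   `result`, a one-row tibble with cost components, `total_cost`,
#'   `qol_score`, `improved_duration` and add-on cost columns.
#' @export
run_cohort <- function(arm, params) {
  validate_params(params)
  if (is.character(arm)) {
    nm <- vapply(params$arms, `[[`, "", "name")
    idx <- match(arm, nm)
    if (is.na(idx)) stop("unknown arm '", arm, "'", call. = FALSE)
    arm <- params$arms[[idx]]
  }
  eng <- cohort_engine(arm$responder_proportion, arm$drug_cost_per_cycle,
                       engine_pars(params))
  s <- eng$sums
  res <- tibble::tibble(
    arm = arm$name,
    medical_cost = s[["medical"]],
    caregiving_cost = s[["caregiving"]],
    productivity_cost = s[["productivity"]],
    total_cost = s[["medical"]] + s[["caregiving"]] + s[["productivity"]],
    qol_score = s[["qol"]] / params$settings$n_cycles,
    improved_duration = s[["duration"]],
    addon_stimulant_cost = s[["stimulant"]],
    addon_osmotic_cost = s[["osmotic"]]
  )
  structure(list(arm = arm$name, trace = eng$trace, eff = eng$eff, result = res),
            class = "cic_arm_result")
}

#' Run all arms of a parameter set
#'
#' @param params A `cic_params` object.
#' @return Tibble with one row per arm (columns as in [run_cohort()]'s
#'   `result`).
#' @export
run_arms <- function(params) {
  do.call(rbind, lapply(params$arms, function(a) run_cohort(a, params)$result))
}

#' Compare arms against the reference
#'
#' Adds `(arm - reference)` deltas for total cost, QoL score and improved
#' duration; the reference's deltas are 0. A positive cost or QoL delta means
#' the arm is more expensive, respectively worse (PAC-QoL is a severity
#' score: lower is better).
#'
#' @param results Tibble from [run_arms()].
#' @param reference Name of the reference arm.
#' @return `results` with `d_total_cost`, `d_qol`, `d_duration` columns.
#' @export
compare_arms <- function(results, reference) {
  i <- match(reference, results$arm)
  if (is.na(i)) stop("reference arm '", reference, "' not in results", call. = FALSE)
  results$d_total_cost <- results$total_cost - results$total_cost[i]
  results$d_qol <- results$qol_score - results$qol_score[i]
  results$d_duration <- results$improved_duration - results$improved_duration[i]
  results
}

#' Run the base-case analysis
#'
#' Runs every arm and appends deltas versus the configured reference arm.
#'
#' @param params A `cic_params` object (default: the shipped base case).
#' @return Tibble with one row per arm, including delta columns.
#' @export
run_base_case <- function(params = base_case_params()) {
  compare_arms(run_arms(params), params$reference_arm)
}
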