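#' Convert an annual probability to a per-cycle probability
#'
#' Standard rate conversion assuming a constant hazard within the year:
#' `1 - (1 - p_annual)^(cycle_days / days_per_year)`.
#'
#' @param p_annual Annual probability, in `[0, 1)`.
#' @param cycle_days Cycle length in days.
#' @param days_per_year Days per year (default 365).
#' @return Per-cycle probability.
#' @examples
#' annual_prob_to_cycle(0.15, 28)   # ~0.0124, the per-cycle relapse probability
#' annual_prob_to_cycle(0.0129, 28) # ~0.0010, the per-cycle mortality probability
#' @export
annual_prob_to_cycle <- function(p_annual, cycle_days = 28, days_per_year = 365) {
  if (any(p_annual < 0 | p_annual >= 1)) {
    stop("`p_annual` must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(cycle_days > 0, days_per_year > 0)
  1 - (1 - p_annual)^(cycle_days / days_per_year)
}

#' Apply a risk ratio to a reference responder proportion
#'
#' @param p_reference Responder proportion of the reference arm, in (0, 1).
#' @param rr Risk ratio versus the reference arm (positive; 1 for the
#'   reference itself).
#' @return `p_reference * rr`, a probability.
#' @examples
#' apply_risk_ratio(0.6012458, 0.8829) # lubiprostone 48 ug responder proportion
#' @export
apply_risk_ratio <- function(p_reference, rr) {
  if (any(p_reference <= 0 | p_reference >= 1)) {
    stop("`p_reference` must lie in (0, 1)", call. = FALSE)
  }
  if (any(rr <= 0)) stop("`rr` must be positive", call. = FALSE)
  out <- p_reference * rr
  if (any(out > 1)) stop("`p_reference * rr` exceeds 1", call. = FALSE)
  out
}

#' Caregiving cost per cycle for one health state
#'
#' Product of the proportion of patients aged >= 65, the fraction of a 7-hour
#' caregiver workday spent on defecation management in the given state, the
#' proportion of the aged population needing daily care that includes
#' defecation management, and the average wage per cycle.
#'
#' @param components Named list of cost components (see [cic_params()]).
#' @param state `"improved"` or `"unimproved"`.
#' @return Cost in JPY per cycle.
#' @export
derive_caregiving_cost <- function(components, state = c("improved", "unimproved")) {
  state <- match.arg(state)
  frac <- switch(state,
    improved = components$care_time_frac_improved,
    unimproved = components$care_time_frac_unimproved
  )
  components$prop_age_ge65 * frac * components$prop_needing_care *
    components$avg_wage_per_cycle
}

#' Productivity loss per cycle for one health state
#'
#' Product of the proportion of patients under 65 (assumed of working age),
#' the overall work-productivity impairment for the state, and the average
#' wage per cycle.
#'
#' @inheritParams derive_caregiving_cost
#' @return Cost in JPY per cycle.
#' @export
derive_productivity_loss <- function(components, state = c("improved", "unimproved")) {
  state <- match.arg(state)
  imp <- switch(state,
    improved = components$impairment_improved,
    unimproved = components$impairment_unimproved
  )
  (1 - components$prop_age_ge65) * imp * components$avg_wage_per_cycle
}

#' Model settings
#'
#' @param cycle_length_days Cycle length in days (base case 28).
#' @param n_cycles Number of cycles in the horizon (base case 26 = 2 years).
#' @param annual_discount_rate Annual discount rate for costs and QoL
#'   (base case 0.02).
#' @param days_per_year Days per year used in rate conversion and discounting.
#' @param discount_timing `"cycle-end"` discounts cycle t's accrual by elapsed
#'   time (t+1) cycles; `"cycle-start"` by t cycles.
#' @param cycle_convention `"mortality-first"` resolves deaths at the start of
#'   each cycle so that survivors accrue that cycle's payoffs;
#'   `"accrue-first"` accrues with the start-of-cycle distribution and applies
#'   all transitions afterwards.
#' @param use_rounded_cycle_probs Use the 4-dp rounded per-cycle probabilities
#'   (0.0124 relapse, 0.0010 mortality) instead of the full-precision
#'   conversions.
#' @return A `cic_settings` list.
#' @export
cic_settings <- function(cycle_length_days = 28, n_cycles = 26,
                         annual_discount_rate = 0.02, days_per_year = 365,
                         discount_timing = c("cycle-end", "cycle-start"),
                         cycle_convention = c("mortality-first", "accrue-first"),
                         use_rounded_cycle_probs = FALSE) {
  discount_timing <- match.arg(discount_timing)
  cycle_convention <- match.arg(cycle_convention)
  stopifnot(
    cycle_length_days > 0, n_cycles >= 1,
    annual_discount_rate >= 0, annual_discount_rate < 1, days_per_year > 0
  )
  structure(
    list(
      cycle_length_days = cycle_length_days, n_cycles = as.integer(n_cycles),
      annual_discount_rate = annual_discount_rate, days_per_year = days_per_year,
      discount_timing = discount_timing, cycle_convention = cycle_convention,
      use_rounded_cycle_probs = isTRUE(use_rounded_cycle_probs)
    ),
    class = "cic_settings"
  )
}

#' Treatment arm
#'
#' @param name Arm identifier.
#' @param drug_cost_per_cycle Drug acquisition cost, JPY per 28-day cycle.
#' @param responder_proportion Proportion achieving >= 3 spontaneous bowel
#'   movements per week, in (0, 1).
#' @param risk_ratio_vs_reference Efficacy risk ratio versus the reference arm.
#' @return A `cic_arm` list.
#' @export
cic_arm <- function(name, drug_cost_per_cycle, responder_proportion,
                    risk_ratio_vs_reference = 1.0) {
  stopifnot(
    is.character(name), nchar(name) > 0,
    drug_cost_per_cycle >= 0,
    responder_proportion > 0, responder_proportion < 1,
    risk_ratio_vs_reference > 0
  )
  structure(
    list(
      name = name, drug_cost_per_cycle = drug_cost_per_cycle,
      responder_proportion = responder_proportion,
      risk_ratio_vs_reference = risk_ratio_vs_reference
    ),
    class = "cic_arm"
  )
}

#' Assemble a full model parameter set
#'
#' Collects settings, treatment arms, transition inputs, QoL scores and cost
#' inputs, derives the per-cycle quantities (cycle transition probabilities,
#' caregiving and productivity costs per cycle) and validates the result.
#'
#' @param settings A [cic_settings()] object.
#' @param arms List of [cic_arm()] objects.
#' @param reference_arm Name of the reference arm for comparisons.
#' @param transitions Named list: `annual_relapse_prob`,
#'   `annual_mortality_prob`, `unimproved_mortality_multiplier`.
#' @param qol Named list: `improved_score`, `unimproved_score` (PAC-QoL points;
#'   higher is worse).
#' @param costs Named list of direct per-cycle costs: `disimpaction_per_cycle`,
#'   `enema_per_cycle`, `addon_stimulant_per_cycle`, `addon_osmotic_per_cycle`.
#' @param cost_components Named list of caregiving/productivity components
#'   (see the shipped `base_case.yaml` for the fields).
#' @param addon Add-on treatment block (tunnel-state extension); disabled in
#'   the base case.
#' @param derived Optional overrides for the derived per-cycle costs; used by
#'   the sensitivity analyses. Any of `caregiving_improved_per_cycle`,
#'   `caregiving_unimproved_per_cycle`, `productivity_improved_per_cycle`,
#'   `productivity_unimproved_per_cycle`.
#' @return A validated `cic_params` object.
#' @export
cic_params <- function(settings = cic_settings(), arms, reference_arm,
                       transitions, qol, costs, cost_components,
                       addon = list(enabled = FALSE, cycles_before_addon = 3,
                                    improvement_prob = 0.04,
                                    improvement_time_unit = "cycle"),
                       derived = list()) {
  p <- structure(
    list(
      settings = settings, arms = arms, reference_arm = reference_arm,
      transitions = transitions, qol = qol, costs = costs,
      cost_components = cost_components, addon = addon
    ),
    class = "cic_params"
  )
  p <- derive_params(p, derived)
  validate_params(p)
  p
}

# Fill in the per-cycle quantities implied by the raw inputs.
derive_params <- function(p, overrides = list()) {
  s <- p$settings
  tr <- p$transitions
  tr$cycle_relapse_prob <- annual_prob_to_cycle(
    tr$annual_relapse_prob, s$cycle_length_days, s$days_per_year
  )
  tr$cycle_mortality_prob <- annual_prob_to_cycle(
    tr$annual_mortality_prob, s$cycle_length_days, s$days_per_year
  )
  if (isTRUE(s$use_rounded_cycle_probs)) {
    tr$cycle_relapse_prob <- round(tr$cycle_relapse_prob, 4)
    tr$cycle_mortality_prob <- round(tr$cycle_mortality_prob, 4)
  }
  p$transitions <- tr

  cc <- p$cost_components
  d <- list(
    caregiving_improved_per_cycle = derive_caregiving_cost(cc, "improved"),
    caregiving_unimproved_per_cycle = derive_caregiving_cost(cc, "unimproved"),
    productivity_improved_per_cycle = derive_productivity_loss(cc, "improved"),
    productivity_unimproved_per_cycle = derive_productivity_loss(cc, "unimproved")
  )
  d[names(overrides)] <- overrides
  p$costs[names(d)] <- d
  p
}

#' Validate a model parameter set
#'
#' Checks type and range invariants (probabilities in range, non-negative
#' costs, unimproved burden at least the improved burden, reference arm
#' present). Called by [cic_params()]; exported so perturbed sets can be
#' re-checked.
#'
#' @param p A `cic_params` object.
#' @return `p`, invisibly; errors describe the first violated invariant.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "cic_params"))
  tr <- p$transitions
  probs <- c(
    tr$annual_relapse_prob, tr$annual_mortality_prob,
    tr$cycle_relapse_prob, tr$cycle_mortality_prob
  )
  if (any(probs < 0 | probs > 1)) stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  if (tr$cycle_relapse_prob > tr$annual_relapse_prob + 1e-12 ||
      tr$cycle_mortality_prob > tr$annual_mortality_prob + 1e-12) {
    stop("cycle probabilities cannot exceed their annual counterparts", call. = FALSE)
  }
  if (tr$unimproved_mortality_multiplier <= 0) {
    stop("`unimproved_mortality_multiplier` must be positive", call. = FALSE)
  }
  q <- p$qol
  if (any(c(q$improved_score, q$unimproved_score) < 0) ||
      any(c(q$improved_score, q$unimproved_score) > 4)) {
    stop("PAC-QoL scores must lie in [0, 4]", call. = FALSE)
  }
  if (q$unimproved_score < q$improved_score) {
    stop("unimproved PAC-QoL must be >= improved (higher is worse)", call. = FALSE)
  }
  co <- p$costs
  cost_fields <- c(
    "disimpaction_per_cycle", "enema_per_cycle",
    "addon_stimulant_per_cycle", "addon_osmotic_per_cycle",
    "caregiving_improved_per_cycle", "caregiving_unimproved_per_cycle",
    "productivity_improved_per_cycle", "productivity_unimproved_per_cycle"
  )
  miss <- setdiff(cost_fields, names(co))
  if (length(miss)) stop("missing cost fields: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(unlist(co[cost_fields]) < 0)) stop("costs must be non-negative", call. = FALSE)
  if (co$caregiving_unimproved_per_cycle < co$caregiving_improved_per_cycle ||
      co$productivity_unimproved_per_cycle < co$productivity_improved_per_cycle) {
    stop("unimproved caregiving/productivity costs must be >= improved", call. = FALSE)
  }
  cc <- p$cost_components
  fracs <- unlist(cc[setdiff(names(cc), "avg_wage_per_cycle")])
  if (any(fracs < 0 | fracs > 1)) stop("cost-component fractions must lie in [0, 1]", call. = FALSE)
  if (cc$avg_wage_per_cycle <= 0) stop("`avg_wage_per_cycle` must be positive", call. = FALSE)
  if (!is.list(p$arms) || !length(p$arms)) stop("at least one arm is required", call. = FALSE)
  nm <- vapply(p$arms, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("arm names must be unique", call. = FALSE)
  if (!p$reference_arm %in% nm) {
    stop("reference arm '", p$reference_arm, "' not among arms", call. = FALSE)
  }
  invisible(p)
}

#' Read a model parameter file
#'
#' Parses a YAML configuration (schema: the shipped `base_case.yaml`),
#' derives per-cycle quantities and validates.
#'
#' @param path Path to a YAML parameter file.
#' @return A `cic_params` object.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  req <- c("settings", "arms", "reference_arm", "transitions", "qol",
           "costs", "cost_components")
  miss <- setdiff(req, names(raw))
  if (length(miss)) {
    stop("config is missing sections: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  settings <- do.call(cic_settings, raw$settings)
  arms <- lapply(raw$arms, function(a) do.call(cic_arm, a))
  addon <- raw$addon %||% list(enabled = FALSE, cycles_before_addon = 3,
                               improvement_prob = 0.04,
                               improvement_time_unit = "cycle")
  cic_params(
    settings = settings, arms = arms, reference_arm = raw$reference_arm,
    transitions = raw$transitions, qol = raw$qol, costs = raw$costs,
    cost_components = raw$cost_components, addon = addon
  )
}

#' Write a model parameter set to YAML
#'
#' Serializes the raw inputs (not the derived per-cycle quantities, which are
#' recomputed on read) so that `read_params(write_params(p, f))` round-trips.
#'
#' @param p A `cic_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "cic_params"))
  derived <- c(
    "caregiving_improved_per_cycle", "caregiving_unimproved_per_cycle",
    "productivity_improved_per_cycle", "productivity_unimproved_per_cycle"
  )
  out <- list(
    settings = unclass(p$settings),
    reference_arm = p$reference_arm,
    arms = lapply(p$arms, unclass),
    transitions = p$transitions[c("annual_relapse_prob", "annual_mortality_prob",
                                  "unimproved_mortality_multiplier")],
    qol = p$qol,
    costs = p$costs[setdiff(names(p$costs), derived)],
    cost_components = p$cost_components,
    addon = p$addon
  )
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' The shipped base-case parameter set
#'
#' @param ... Overrides forwarded to [cic_settings()] (e.g.
#'   `annual_discount_rate = 0`).
#' @return A `cic_params` object with all base-case inputs.
#' @export
base_case_params <- function(...) {
  p <- read_params(system.file("extdata", "base_case.yaml", package = "ciccea",
                               mustWork = TRUE))
  dots <- list(...)
  if (length(dots)) {
    s <- unclass(p$settings)
    s[names(dots)] <- dots
    p$settings <- do.call(cic_settings, s)
    p <- derive_params(p)
    validate_params(p)
  }
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cic_params <- function(x, ...) {
  s <- x$settings
  cat("<cic_params> ", length(x$arms), " arms, ", s$n_cycles, " cycles of ",
      s$cycle_length_days, " days, discount ",
      100 * s$annual_discount_rate, "%/year (", s$discount_timing, ", ",
      s$cycle_convention, ")\n", sep = "")
  for (a in x$arms) {
    cat(sprintf("  %-18s drug %8.1f JPY/cycle  responders %.7f\n",
                a$name, a$drug_cost_per_cycle, a$responder_proportion))
  }
  invisible(x)
}
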