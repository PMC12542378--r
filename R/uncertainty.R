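#' One-way deterministic sensitivity analysis
#'
#' Varies one parameter group at a time by `-perturbation` and
#' `+perturbation` (base case +/-20%), holding everything else fixed, and
#' re-runs all arms. Groups follow the published one-way analysis: each arm's
#' efficacy (responder proportion), the PAC-QoL pair, the bowel-management
#' procedure costs, each arm's drug cost, the productivity-loss pair and the
#' caregiving-cost pair. Probabilities pushed above 1 are clamped with a
#' warning.
#'
#' @param params A `cic_params` object.
#' @param perturbation Relative perturbation in (0, 1); default 0.2.
#' @param groups Named list of modifier functions `function(params, factor)`,
#'   defaulting to [dsa_groups()]. Pass `dsa_groups(params, per_scalar =
#'   TRUE)` for one group per scalar input.
#' @return Long tibble: `group`, `direction` (`lower`/`upper`), one row per
#'   arm with `total_cost`, `qol_score` and deltas versus the reference arm.
#' @export
run_dsa <- function(params, perturbation = 0.2, groups = dsa_groups(params)) {
  stopifnot(perturbation > 0, perturbation < 1)
  out <- lapply(names(groups), function(g) {
    rows <- lapply(c(lower = 1 - perturbation, upper = 1 + perturbation),
                   function(f) {
      res <- run_base_case(groups[[g]](params, f))
      res$group <- g
      res$direction <- if (f < 1) "lower" else "upper"
      res
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  out[, c("group", "direction", setdiff(names(out), c("group", "direction")))]
}

#' Parameter groupings for the one-way sensitivity analysis
#'
#' @param params A `cic_params` object.
#' @param per_scalar If `TRUE`, return one group per scalar input instead of
#'   the nine published row groups.
#' @return Named list of modifier functions `function(params, factor)`.
#' @export
dsa_groups <- function(params, per_scalar = FALSE) {
  arm_names <- vapply(params$arms, `[[`, "", "name")
  scale_costs <- function(fields) {
    force(fields)
    function(p, f) {
      p$costs[fields] <- lapply(p$costs[fields], `*`, f)
      validate_params(p)
      p
    }
  }
  scale_efficacy <- function(arm) {
    force(arm)
    function(p, f) {
      i <- match(arm, vapply(p$arms, `[[`, "", "name"))
      p$arms[[i]]$responder_proportion <-
        clamp_prob(p$arms[[i]]$responder_proportion * f, "responder proportion")
      p
    }
  }
  scale_drug <- function(arm) {
    force(arm)
    function(p, f) {
      i <- match(arm, vapply(p$arms, `[[`, "", "name"))
      p$arms[[i]]$drug_cost_per_cycle <- p$arms[[i]]$drug_cost_per_cycle * f
      p
    }
  }
  groups <- list()
  for (a in arm_names) groups[[paste0("efficacy_", a)]] <- scale_efficacy(a)
  groups$qol <- function(p, f) {
    p$qol$improved_score <- p$qol$improved_score * f
    p$qol$unimproved_score <- p$qol$unimproved_score * f
    p
  }
  groups$medical_cost <- scale_costs(c("disimpaction_per_cycle", "enema_per_cycle"))
  for (a in arm_names) groups[[paste0("drug_cost_", a)]] <- scale_drug(a)
  groups$productivity_loss <- scale_costs(c("productivity_improved_per_cycle",
                                            "productivity_unimproved_per_cycle"))
  groups$caregiving_cost <- scale_costs(c("caregiving_improved_per_cycle",
                                          "caregiving_unimproved_per_cycle"))
  if (per_scalar) {
    sing <- list()
    for (a in arm_names) {
      sing[[paste0("efficacy_", a)]] <- groups[[paste0("efficacy_", a)]]
      sing[[paste0("drug_cost_", a)]] <- groups[[paste0("drug_cost_", a)]]
    }
    sing$qol_improved <- function(p, f) { p$qol$improved_score <- p$qol$improved_score * f; p }
    sing$qol_unimproved <- function(p, f) { p$qol$unimproved_score <- p$qol$unimproved_score * f; p }
    for (fld in c("disimpaction_per_cycle", "enema_per_cycle",
                  "caregiving_improved_per_cycle", "caregiving_unimproved_per_cycle",
                  "productivity_improved_per_cycle", "productivity_unimproved_per_cycle")) {
      sing[[fld]] <- scale_costs(fld)
    }
    return(sing)
  }
  groups
}

clamp_prob <- function(x, what) {
  if (x >= 1) {
    warning(what, " perturbed to ", signif(x, 6), "; clamped below 1",
            call. = FALSE)
    x <- 1 - 1e-9
  }
  x
}

#' Default probabilistic-sensitivity-analysis distributions
#'
#' A conventional assignment: beta (moment-matched) for probabilities and
#' proportions, gamma for unit costs, normal for PAC-QoL scores, lognormal
#' for the efficacy risk ratios. The SD defaults to `cv` times the mean.
#' Comparator responder proportions are scaled per draw by the relative
#' movement of the sampled reference proportion and risk ratio, so efficacy
#' uncertainty is propagated the way the point estimates were derived while
#' zero-variance draws reproduce the configured proportions exactly. Fully replaceable:
#' pass any list of `list(name, family, mean, sd)` entries (family `"fixed"`
#' ignores `sd`) to [run_psa()].
#'
#' @param params A `cic_params` object.
#' @param cv Coefficient of variation applied where no standard error is
#'   available (default 0.10).
#' @return Named list of distribution specs.
#' @export
default_psa_distributions <- function(params, cv = 0.10) {
  ref <- params$reference_arm
  arm_names <- vapply(params$arms, `[[`, "", "name")
  spec <- list()
  add <- function(name, family, mean) {
    spec[[name]] <<- list(name = name, family = family, mean = mean,
                          sd = cv * mean)
  }
  ref_arm <- params$arms[[match(ref, arm_names)]]
  add("responder_reference", "beta", ref_arm$responder_proportion)
  for (a in params$arms) {
    if (a$name != ref) add(paste0("rr_", a$name), "lognormal", a$risk_ratio_vs_reference)
  }
  add("annual_relapse_prob", "beta", params$transitions$annual_relapse_prob)
  add("annual_mortality_prob", "beta", params$transitions$annual_mortality_prob)
  add("qol_improved", "normal", params$qol$improved_score)
  add("qol_unimproved", "normal", params$qol$unimproved_score)
  for (a in params$arms) add(paste0("drug_cost_", a$name), "gamma", a$drug_cost_per_cycle)
  for (fld in c("disimpaction_per_cycle", "enema_per_cycle",
                "caregiving_improved_per_cycle", "caregiving_unimproved_per_cycle",
                "productivity_improved_per_cycle", "productivity_unimproved_per_cycle")) {
    add(fld, "gamma", params$costs[[fld]])
  }
  spec
}

sample_distribution <- function(d, n) {
  m <- d$mean
  sd <- d$sd
  if (identical(d$family, "fixed") || sd == 0 || m == 0) return(rep(m, n))
  switch(d$family,
    beta = {
      v <- sd^2
      if (v >= m * (1 - m)) stop("beta variance too large for '", d$name, "'", call. = FALSE)
      k <- m * (1 - m) / v - 1
      stats::rbeta(n, m * k, (1 - m) * k)
    },
    gamma = stats::rgamma(n, shape = (m / sd)^2, rate = m / sd^2),
    normal = stats::rnorm(n, m, sd),
    lognormal = {
      sdl <- sqrt(log(1 + (sd / m)^2))
      stats::rlnorm(n, log(m) - sdl^2 / 2, sdl)
    },
    stop("unknown distribution family '", d$family, "'", call. = FALSE)
  )
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo draws from the assigned parameter distributions; all arms are
#' evaluated on each draw with common sampled values for the shared
#' parameters (transition probabilities, QoL scores, procedure, caregiving
#' and productivity costs). Parameters are sampled parameter-major under one
#' seed, so adding arms or draws does not reshuffle earlier draws of other
#' parameters.
#'
#' @param params A `cic_params` object.
#' @param n_draws Number of Monte-Carlo draws (the published analysis used
#'   10,000).
#' @param seed Integer master seed.
#' @param distributions Distribution assignment, default
#'   [default_psa_distributions()].
#' @return A `cic_psa` list: `samples` (tibble: `draw`, `arm`, `total_cost`,
#'   `qol_score`), `parameters` (tibble of the sampled inputs per draw),
#'   `summary` (one row per comparison from [ce_plane_summary()]),
#'   `reference`, `n_draws`, `seed`.
#' @export
run_psa <- function(params, n_draws = 10000, seed = 1L,
                    distributions = default_psa_distributions(params)) {
  stopifnot(n_draws >= 1)
  validate_params(params)
  draws <- with_seed(seed, {
    vals <- lapply(distributions, sample_distribution, n = n_draws)
    names(vals) <- names(distributions)
    vals
  })
  s <- params$settings
  base_eng <- engine_pars(params)
  arm_names <- vapply(params$arms, `[[`, "", "name")
  ref <- params$reference_arm

  get_draw <- function(name, i, fallback) {
    if (!is.null(draws[[name]])) draws[[name]][i] else fallback
  }
  cost <- matrix(NA_real_, n_draws, length(arm_names),
                 dimnames = list(NULL, arm_names))
  qol <- cost
  for (i in seq_len(n_draws)) {
    eng <- base_eng
    relapse_a <- get_draw("annual_relapse_prob", i, params$transitions$annual_relapse_prob)
    mort_a <- get_draw("annual_mortality_prob", i, params$transitions$annual_mortality_prob)
    eng$relapse <- annual_prob_to_cycle(min(relapse_a, 1 - 1e-12),
                                        s$cycle_length_days, s$days_per_year)
    eng$mort <- annual_prob_to_cycle(min(mort_a, 1 - 1e-12),
                                     s$cycle_length_days, s$days_per_year)
    eng$qol_i <- max(get_draw("qol_improved", i, params$qol$improved_score), 0)
    eng$qol_u <- max(get_draw("qol_unimproved", i, params$qol$unimproved_score), 0)
    eng$proc <- get_draw("disimpaction_per_cycle", i, params$costs$disimpaction_per_cycle) +
      get_draw("enema_per_cycle", i, params$costs$enema_per_cycle)
    eng$cg_i <- get_draw("caregiving_improved_per_cycle", i, params$costs$caregiving_improved_per_cycle)
    eng$cg_u <- get_draw("caregiving_unimproved_per_cycle", i, params$costs$caregiving_unimproved_per_cycle)
    eng$pr_i <- get_draw("productivity_improved_per_cycle", i, params$costs$productivity_improved_per_cycle)
    eng$pr_u <- get_draw("productivity_unimproved_per_cycle", i, params$costs$productivity_unimproved_per_cycle)
    p_ref_base <- params$arms[[match(ref, arm_names)]]$responder_proportion
    p_ref <- get_draw("responder_reference", i, p_ref_base)
    for (a in params$arms) {
      p_arm <- if (a$name == ref) p_ref else {
        rr <- get_draw(paste0("rr_", a$name), i, a$risk_ratio_vs_reference)
        min(a$responder_proportion * (p_ref / p_ref_base) *
              (rr / a$risk_ratio_vs_reference), 1 - 1e-9)
      }
      dc <- get_draw(paste0("drug_cost_", a$name), i, a$drug_cost_per_cycle)
      sums <- cohort_engine(p_arm, dc, eng)$sums
      cost[i, a$name] <- sums[["medical"]] + sums[["caregiving"]] + sums[["productivity"]]
      qol[i, a$name] <- sums[["qol"]] / s$n_cycles
    }
  }
  samples <- tibble::tibble(
    draw = rep(seq_len(n_draws), times = length(arm_names)),
    arm = rep(arm_names, each = n_draws),
    total_cost = as.vector(cost),
    qol_score = as.vector(qol)
  )
  psa <- structure(
    list(samples = samples,
         parameters = tibble::as_tibble(c(list(draw = seq_len(n_draws)), draws)),
         reference = ref, n_draws = n_draws, seed = seed),
    class = "cic_psa"
  )
  comparators <- setdiff(arm_names, ref)
  psa$summary <- do.call(rbind, lapply(comparators, function(a) ce_plane_summary(psa, a)))
  psa
}

#' Cost-effectiveness-plane summary for one comparison
#'
#' For each draw, computes the comparator-minus-reference differences in
#' total cost and QoL score, and summarizes the plane: the proportion of
#' draws in which the reference arm has better QoL (strictly lower PAC-QoL
#' score), lower cost, and both, plus equal-tailed 95% credible intervals of
#' the differences.
#'
#' @param psa A `cic_psa` object from [run_psa()], or its `samples` tibble.
#' @param comparison Name of the comparator arm.
#' @param reference Reference arm (defaults to the PSA's stored reference).
#' @return One-row tibble: `comparison`, `n_draws`, `ref_better_qol`,
#'   `ref_lower_cost`, `ref_better_both`, `d_cost_lo`, `d_cost_hi`,
#'   `d_qol_lo`, `d_qol_hi` (2.5/97.5 percentiles of comparator - reference).
#' @export
ce_plane_summary <- function(psa, comparison, reference = NULL) {
  samples <- if (inherits(psa, "cic_psa")) psa$samples else psa
  reference <- reference %||% (if (inherits(psa, "cic_psa")) psa$reference else NULL)
  if (is.null(reference)) stop("`reference` is required", call. = FALSE)
  if (!nrow(samples)) stop("empty PSA sample set", call. = FALSE)
  ref <- samples[samples$arm == reference, ]
  cmp <- samples[samples$arm == comparison, ]
  if (!nrow(cmp)) stop("comparison arm '", comparison, "' not in samples", call. = FALSE)
  stopifnot(identical(ref$draw, cmp$draw))
  d_cost <- cmp$total_cost - ref$total_cost
  d_qol <- cmp$qol_score - ref$qol_score
  better_qol <- ref$qol_score < cmp$qol_score
  lower_cost <- ref$total_cost < cmp$total_cost
  ci <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  cc <- ci(d_cost); cq <- ci(d_qol)
  tibble::tibble(
    comparison = comparison, n_draws = nrow(ref),
    ref_better_qol = mean(better_qol),
    ref_lower_cost = mean(lower_cost),
    ref_better_both = mean(better_qol & lower_cost),
    d_cost_lo = cc[1], d_cost_hi = cc[2],
    d_qol_lo = cq[1], d_qol_hi = cq[2]
  )
}
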