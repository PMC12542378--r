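#' Round a result table to the published precision
#'
#' Costs to integer JPY, QoL scores and durations to 3 decimals; proportions
#' are left untouched. With `pretty = TRUE`, costs are additionally rendered
#' as character with thousands separators (for display; the default keeps
#' machine-readable numerics).
#'
#' @param t A result tibble (base case, DSA, scenario or PSA summary).
#' @param pretty Render costs with thousands separators.
#' @return The table with rounding applied at serialization precision.
#' @export
format_table <- function(t, pretty = FALSE) {
  out <- t
  for (nm in names(out)) {
    if (!is.numeric(out[[nm]])) next
    if (grepl("cost|_lo$|_hi$", nm) && !grepl("qol", nm)) {
      out[[nm]] <- round(out[[nm]])
      if (pretty) out[[nm]] <- format(out[[nm]], big.mark = ",", trim = TRUE,
                                      scientific = FALSE)
    } else if (grepl("qol|duration", nm)) {
      out[[nm]] <- round(out[[nm]], 3)
    }
  }
  out
}

#' Run an analysis end to end and write its outputs
#'
#' Reads a parameter file (default: the shipped base case), runs the
#' requested analysis, and writes the result tables as CSV and JSON together
#' with a plain-text log of every effective parameter (including the derived
#' per-cycle probabilities and costs, the resolved convention flags and the
#' seed).
#'
#' @param config_path Path to a YAML parameter file; `NULL` for the shipped
#'   base case.
#' @param analysis One of `"base"`, `"dsa"`, `"psa"`, `"scenario"`.
#' @param out_dir Output directory (created if needed).
#' @param id Scenario id (1-6), for `analysis = "scenario"`.
#' @param option Scenario option (e.g. discount rate for scenario 2, horizon
#'   years for scenario 4).
#' @param seed Integer seed (used by the PSA).
#' @param n_draws PSA draws.
#' @param perturbation DSA perturbation (default 0.2).
#' @param pretty Also write a pretty text rendering with thousands
#'   separators.
#' @return Invisibly, a character vector of the files written.
#' @export
run_pipeline <- function(config_path = NULL,
                         analysis = c("base", "dsa", "psa", "scenario"),
                         out_dir = ".", id = NULL, option = NULL, seed = 1L,
                         n_draws = 10000, perturbation = 0.2, pretty = FALSE) {
  analysis <- match.arg(analysis)
  params <- if (is.null(config_path)) base_case_params() else read_params(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(out_dir, analysis)
  written <- character()
  write_both <- function(df, stem) {
    csv <- paste0(stem, ".csv"); json <- paste0(stem, ".json")
    utils::write.csv(format_table(df), csv, row.names = FALSE)
    jsonlite::write_json(format_table(df), json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    out <- c(csv, json)
    if (pretty) {
      txt <- paste0(stem, "_pretty.txt")
      utils::write.table(format_table(df, pretty = TRUE), txt,
                         row.names = FALSE, quote = FALSE, sep = "  ")
      out <- c(out, txt)
    }
    out
  }
  if (analysis == "base") {
    written <- write_both(run_base_case(params), stem)
  } else if (analysis == "dsa") {
    written <- write_both(run_dsa(params, perturbation), stem)
  } else if (analysis == "psa") {
    psa <- run_psa(params, n_draws = n_draws, seed = seed)
    scatter <- merge(
      psa$samples,
      psa$samples[psa$samples$arm == psa$reference,
                  c("draw", "total_cost", "qol_score")],
      by = "draw", suffixes = c("", "_ref")
    )
    scatter <- scatter[scatter$arm != psa$reference, ]
    scatter$d_cost <- scatter$total_cost - scatter$total_cost_ref
    scatter$d_qol <- scatter$qol_score - scatter$qol_score_ref
    scatter <- scatter[order(scatter$arm, scatter$draw),
                       c("draw", "arm", "d_cost", "d_qol")]
    csv <- paste0(stem, "_scatter.csv")
    utils::write.csv(scatter, csv, row.names = FALSE)
    written <- c(write_both(psa$summary, paste0(stem, "_summary")), csv)
  } else {
    if (is.null(id)) stop("scenario analysis needs `id` (1-6)", call. = FALSE)
    params_s <- apply_scenario(params, id, option)
    res <- run_base_case(params_s)
    res$scenario <- id
    written <- write_both(res, paste0(stem, id))
    params <- params_s
  }
  log_path <- file.path(out_dir, paste0(analysis, if (!is.null(id)) id, "_params.log"))
  writeLines(parameter_log(params, seed = seed, analysis = analysis), log_path)
  invisible(c(written, log_path))
}

# Plain-text dump of every effective parameter, derived value and convention.
parameter_log <- function(params, seed, analysis) {
  s <- params$settings
  tr <- params$transitions
  fmt <- function(x) formatC(x, digits = 10, format = "g")
  c(
    paste0("analysis: ", analysis),
    paste0("seed: ", seed),
    paste0("cycle_length_days: ", s$cycle_length_days),
    paste0("n_cycles: ", s$n_cycles),
    paste0("annual_discount_rate: ", fmt(s$annual_discount_rate)),
    paste0("days_per_year: ", s$days_per_year),
    paste0("discount_timing: ", s$discount_timing),
    paste0("cycle_convention: ", s$cycle_convention),
    paste0("use_rounded_cycle_probs: ", s$use_rounded_cycle_probs),
    paste0("cycle_relapse_prob: ", fmt(tr$cycle_relapse_prob)),
    paste0("cycle_mortality_prob: ", fmt(tr$cycle_mortality_prob)),
    paste0("unimproved_mortality_multiplier: ", fmt(tr$unimproved_mortality_multiplier)),
    paste0("qol_improved: ", fmt(params$qol$improved_score)),
    paste0("qol_unimproved: ", fmt(params$qol$unimproved_score)),
    vapply(names(params$costs), function(nm) {
      paste0("cost.", nm, ": ", fmt(params$costs[[nm]]))
    }, ""),
    vapply(params$arms, function(a) {
      paste0("arm.", a$name, ": drug=", fmt(a$drug_cost_per_cycle),
             " responders=", fmt(a$responder_proportion),
             " rr=", fmt(a$risk_ratio_vs_reference))
    }, ""),
    paste0("addon.enabled: ", isTRUE(params$addon$enabled)),
    paste0("addon.cycles_before_addon: ", params$addon$cycles_before_addon),
    paste0("addon.improvement_prob: ", fmt(params$addon$improvement_prob)),
    paste0("addon.improvement_time_unit: ", params$addon$improvement_time_unit)
  )
}
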