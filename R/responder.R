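#' Closed-form responder proportion under a normal SBM-change model
#'
#' Exact upper-tail probability that weekly spontaneous bowel movements exceed
#' the responder threshold when the synthesized SBM outcome is normal with the
#' given mean and SD: `1 - pnorm((threshold - mean) / sd)`. Serves as the
#' analytic counterpart of [estimate_responder_proportion()].
#'
#' @param mean_sbm Synthesized mean weekly SBM outcome.
#' @param sd_sbm Synthesized SD (positive).
#' @param threshold Responder threshold in SBMs per week (default 3).
#' @return Probability of achieving at least `threshold` SBMs per week.
#' @export
responder_closed_form <- function(mean_sbm, sd_sbm, threshold = 3) {
  if (any(sd_sbm <= 0)) stop("`sd_sbm` must be positive", call. = FALSE)
  stats::pnorm(threshold, mean = mean_sbm, sd = sd_sbm, lower.tail = FALSE)
}

#' Estimate a responder proportion by normal sampling
#'
#' Draws `n_samples` values from a normal distribution with the synthesized
#' mean and SD of the weekly SBM outcome and returns the fraction at or above
#' the responder threshold (>= 3 SBMs/week by default; the boundary is
#' inclusive, a measure-zero choice fixed for reproducibility). This mirrors
#' the sampling procedure used to turn network-meta-analysis summaries into
#' the per-arm responder proportions.
#'
#' @inheritParams responder_closed_form
#' @param n_samples Number of draws (the published analysis used 1000).
#' @param seed Integer seed; mandatory so results are reproducible.
#' @return Estimated responder proportion.
#' @seealso [responder_closed_form()] for the analytic limit.
#' @export
estimate_responder_proportion <- function(mean_sbm, sd_sbm, threshold = 3,
                                          n_samples = 1000, seed) {
  if (sd_sbm <= 0) stop("`sd_sbm` must be positive", call. = FALSE)
  if (n_samples < 1) stop("`n_samples` must be >= 1", call. = FALSE)
  if (missing(seed)) stop("`seed` is required for reproducibility", call. = FALSE)
  with_seed(seed, {
    x <- stats::rnorm(n_samples, mean = mean_sbm, sd = sd_sbm)
    mean(x >= threshold)
  })
}

#' Responder proportions for a table of SBM summaries
#'
#' @param summaries Data frame with columns `arm`, `mean_sbm`, `sd_sbm`
#'   (e.g. from [generate_sbm_summaries()] or a small CSV).
#' @param threshold Responder threshold in SBMs per week.
#' @param n_samples Draws per arm; `Inf` uses the closed form.
#' @param seed Integer seed (per-arm substreams are derived from it).
#' @return Tibble with columns `arm` and `responder_proportion`.
#' @export
responder_proportions <- function(summaries, threshold = 3, n_samples = 1000,
                                  seed = 1L) {
  stopifnot(all(c("arm", "mean_sbm", "sd_sbm") %in% names(summaries)))
  prop <- vapply(seq_len(nrow(summaries)), function(i) {
    if (is.infinite(n_samples)) {
      responder_closed_form(summaries$mean_sbm[i], summaries$sd_sbm[i], threshold)
    } else {
      estimate_responder_proportion(
        summaries$mean_sbm[i], summaries$sd_sbm[i], threshold,
        n_samples, seed = seed + i
      )
    }
  }, numeric(1))
  tibble::tibble(arm = summaries$arm, responder_proportion = prop)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
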