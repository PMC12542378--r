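# Shared fixtures: the base-case parameter set is read once per test run.
base_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- base_case_params()
    cache
  }
})

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

arm_row <- function(results, arm) results[results$arm == arm, ]
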