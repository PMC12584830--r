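# Shared fixtures. The reference set is built once per test run.
ref_ps <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- reference_parameters(quiet = TRUE)
    cache
  }
})

# A strategy-model-shaped list for hand-built engine scenarios.
toy_strategy <- function(matrix = diag(8), death = rep(0, 8),
                         first_cv = rep(0, 8), subsequent_cv = 0,
                         ae = c(hyperkalemia = 0, aki = 0,
                                discontinuation = 0)) {
  s <- ckd_states()
  dimnames(matrix) <- list(s, s)
  structure(list(strategy = "soc", matrix = matrix,
                 first_cv = stats::setNames(first_cv, s),
                 subsequent_cv = subsequent_cv,
                 death = stats::setNames(death, s),
                 ae = ae, drug_cost_soc = 0, drug_cost_intervention = 0),
            class = "ckd_strategy")
}

# Published Table-5-style reference results used by the acceptance checks.
published_results <- list(
  arms = c(triple_cost = 233692.14, triple_qalys = 4.894,
           sglt2i_cost = 352320.33, sglt2i_qalys = 4.637,
           finerenone_cost = 336645.25, finerenone_qalys = 4.603),
  vs_sglt2i = c(incr_cost = -118628.19, incr_qalys = 0.257, nmb = 187506.53),
  vs_finerenone = c(incr_cost = -102953.11, incr_qalys = 0.291,
                    nmb = 181032.95),
  scenario_4y = c(nmb_vs_sglt2i = 17117.14, nmb_vs_finerenone = 28434.07))
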