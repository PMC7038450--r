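# Shared cohort runs for the end-to-end tests; computed once per test
# session and cached, since several test blocks consume the same
# simulated study.
.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cohort_cache)) {
    assign(key, force(expr), envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

study_cohort <- function() cached("cohort", make_cohort(20, seed = 42))

study_mimic_table <- function() {
  cached("mimic", run_mimic_experiment(study_cohort(), seed = 42))
}

study_nback_run <- function() {
  cached("nback", run_nback_experiment(study_cohort(), behavior_model(),
                                       seed = 42))
}
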