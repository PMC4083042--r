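# The reference simulated study and its pipeline run are expensive
# (minutes); they are computed lazily once per test session and shared by
# the tests that need them.

.ref_cache <- new.env(parent = emptyenv())

reference_study <- function() {
  if (is.null(.ref_cache$study)) {
    .ref_cache$study <- simulate_study(sim_config(seed = 20140630L))
  }
  .ref_cache$study
}

reference_run <- function() {
  if (is.null(.ref_cache$run)) {
    .ref_cache$run <- run_pipeline(reference_study(),
                                   file.path(tempdir(), "refrun"),
                                   plots = FALSE)
  }
  .ref_cache$run
}
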