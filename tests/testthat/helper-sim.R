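# One shared small simulated cohort, built lazily and cached for the
# end-to-end and acceptance tests. Three samples keep the full pipeline run
# within a few tens of seconds; the vignette records the problem sizes.
.sim_cache <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    cfg <- sim_config(seed = 11, n_samples = 3L,
                      pop_sizes = c(AFR = 2L, EUR = 1L),
                      n_chroms = 2L, chrom_len = 120000L,
                      n_insertions = 5L, coverage_depth = 40)
    .sim_cache$sim <- sim_cohort(cfg)
  }
  .sim_cache$sim
}

shared_cohort <- function() {
  if (is.null(.sim_cache$cohort)) {
    sim <- shared_sim()
    calls <- lapply(setNames(sim$samples, sim$samples), function(s)
      run_sample_sim(sim, s)$calls)
    .sim_cache$calls <- calls
    .sim_cache$cohort <- run_cohort(calls, sim$populations)
  }
  .sim_cache$cohort
}

shared_calls <- function() {
  shared_cohort()
  .sim_cache$calls
}

# truth rows expected to survive the definition filters
truth_events <- function(sim) sim$events[is.na(sim$events$decoy), ]
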