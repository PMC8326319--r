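# Shared fixtures: small fully generated sessions and cohorts.

make_session <- function(seed = 1, n_main = 24L, n_starter = 8L,
                         params = agent_params(alpha = 0.3, beta = 0.8),
                         sim_seed = seed + 100L, ...) {
  sch <- generate_schedule(seed, n_main = n_main, n_starter = n_starter)
  sch <- generate_feedback_schedule(sch, seed = seed + 1L, ...)
  sch <- generate_thresholds(sch, seed = seed + 2L)
  simulate_participant(sch, params, seed = sim_seed)
}

tiny_cohort <- function(n_per_group = 2, seed = 7, n_main = 24L,
                        n_starter = 8L, ...) {
  simulate_cohort(n_per_group = n_per_group, seed = seed,
                  n_main = n_main, n_starter = n_starter, ...)
}
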