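# shared fixtures: all built in code, seeded per test

# small-but-honest sampler settings for tests (2 chains, 1000 retained draws)
quick_settings <- function(seed, n_iterations = 1500, n_warmup = 500) {
  sampler_settings(n_chains = 2, n_iterations = n_iterations,
                   n_warmup = n_warmup, seed = seed)
}

# one subject's worth of flange-task trials at the study's size (144 planned)
sim_subject_trials <- function(b_congruent_ms = 0, seed = 1,
                               params = NULL, n_pairs = 72,
                               n_sessions = 6, trials_per_session = 24) {
  if (is.null(params))
    params <- dotprobe_gen_params(b_congruent_ms = b_congruent_ms,
                                  p_anticipatory = 0, p_slow = 0)
  plan <- schedule_dotprobe(stimulus_pairs(n_pairs, "flange"),
                            n_sessions, trials_per_session, seed = seed)
  simulate_dotprobe(plan, params, subject_id = "subj1", seed = seed + 1)
}

# a full preference dataset (6 subjects x 6 sessions)
sim_preference_trials <- function(params = choice_gen_params(), seed = 1,
                                  subjects = sprintf("subj%d", 1:6)) {
  plan <- schedule_preference(subjects, seed = seed)
  simulate_choices(plan, params, seed = seed + 1)
}
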