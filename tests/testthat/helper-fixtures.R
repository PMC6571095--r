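# Small, fast fixtures used across the suite. The miniature network keeps the
# full architecture (E units + one inhibitory unit) but shrinks the
# population and the stimulus timing so that structural tests run in
# milliseconds. Science-level tests use the full-size fiducial network.

tiny_params <- function(...) model_params(n_E = 12, ...)

tiny_stim <- list(onset_interval = 300, duration = 100)

tiny_trial <- function(baseline, W, applied, params, settings, seed = 1L, ...) {
  run_trial(baseline, W, applied, params, settings, seed = seed,
            post_wait = 200, avg_delay = 50, avg_len = 150, ...)
}

tiny_experiment <- function(W, patterns, sequences, params, settings, ...) {
  run_experiment(W, patterns, sequences, params, settings,
                 onset_interval = tiny_stim$onset_interval,
                 duration = tiny_stim$duration,
                 post_wait = 200, avg_delay = 50, avg_len = 150, ...)
}

fiducial_point <- function(...) {
  list(params = model_params(...), wcfg = weight_config(),
       settings = integration_settings())
}

# a state table with perfectly separable, deterministic states: one
# distinctive binary vector per sequence, repeated per repetition
synthetic_state_table <- function(states, n_rep, role = "train") {
  n_seq <- nrow(states)
  bin <- states[rep(seq_len(n_seq), each = n_rep), , drop = FALSE]
  state_table(bin, bin * 100, rep(seq_len(n_seq), each = n_rep),
              rep(seq_len(n_rep), n_seq), role = role)
}

# random binary states keyed by sequence id, fixed seed
random_states <- function(n_seq, n_units, seed, p_on = 0.4) {
  withr::with_seed(seed,
    matrix(as.integer(stats::runif(n_seq * n_units) < p_on), n_seq, n_units))
}
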