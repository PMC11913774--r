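# Shared fixtures: fast configurations for simulation-heavy tests.

# Reduced-order prewhitening used by the Monte-Carlo tests: d = 1 plus an
# AR(1) term is enough to whiten the generator's short blocks, and keeps
# thousands of fits affordable.
fast_cfg <- function() {
  synchrony_config(search = arima_search(p_max = 1, q_max = 0, m = 1,
                                         lambda = "none"))
}

# A short-block coupled dyad.
quick_dyad <- function(gain = 0, dur = 45, seed = NULL, lag = 0) {
  generate_dyad_ibi(coupling_config(
    block_duration_s = dur, coupling_gain = gain,
    coupling_lag_samples = lag, seed = seed
  ))
}

# A small uncoupled (or planted-gain) study on 45 s blocks, one block per
# condition, no baseline: the unit used by the surrogate-null simulations.
quick_study <- function(n_dyads = 8, gain = 0, seed = NULL, ...) {
  generate_study(
    n_dyads, n_blocks_per_condition = 1, block_duration_s = 45,
    include_baseline = FALSE, gain_task = gain, gain_novelty_delta = 0,
    gain_anxiety_slope = 0, coupling = coupling_config(block_duration_s = 45),
    seed = seed, ...
  )
}
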