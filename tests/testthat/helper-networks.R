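# shared builders and lazily cached simulations for the test suite

ref_config <- function(...) network_config(dg_ex = 0.4, ...)

small_config <- function(...) {
  network_config(n_neurons = 100L, dg_ex = 0.4, ...)
}

# raster from explicit spikes
toy_raster <- function(neuron, time, n_neurons = max(neuron), t_start = 0,
                       t_end = max(time) + 1, trial_id = 1L) {
  critnet:::new_spike_raster(neuron, time, n_neurons, t_start, t_end,
                             trial_id = trial_id)
}

# expensive simulations shared across test files, computed on first use
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .sim_cache)) assign(key, force(expr), .sim_cache)
  get(key, .sim_cache)
}

ref_connectivity <- function() {
  cached("conn_ref", build_network(ref_config(), seed = 1))
}

# 60 s of ongoing critical activity at 20 Hz background, with traces
critical_ongoing <- function() {
  cached("ongoing_60s",
         run_trial(ref_connectivity(), ref_config(), background_spec(20),
                   NULL, duration = 60000, seed = 2))
}
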