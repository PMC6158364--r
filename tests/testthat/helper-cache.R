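# Expensive shared objects, built once per test session.
.cache <- new.env(parent = emptyenv())

cached_net <- function() {
  if (is.null(.cache$net))
    .cache$net <- calibrated_network(seed = 1)
  .cache$net
}

cached_amplitude <- function() {
  if (is.null(.cache$amp))
    .cache$amp <- calibrate_pulse_amplitude(make_preset("thalamocortical"))
  .cache$amp
}

# The default frequency sweep (plus DBS-off baseline), 3 seeds x 2 s,
# shared by the metrics and acceptance tests.
cached_sweep <- function() {
  if (is.null(.cache$sweep)) {
    cfg <- simulation_config(duration = 2000, burn_in = 500, seed = 1)
    .cache$sweep <- frequency_sweep(
      cached_net(), frequencies = c(0, default_sweep_frequencies()),
      seeds = 1:3, cfg = cfg, amplitude = cached_amplitude())
  }
  .cache$sweep
}

# A single labeled 60 Hz run reused by attribution tests.
cached_run_60 <- function() {
  if (is.null(.cache$run60)) {
    cfg <- simulation_config(duration = 1500, burn_in = 500, seed = 1)
    train <- make_pulse_train(60, 180, cached_amplitude(), 0, 1500)
    .cache$run60 <- list(
      spikes = attribute_spikes(run_simulation(cached_net(), train, cfg),
                                train),
      train = train)
  }
  .cache$run60
}

# Minimal hand-built spike set for fixture-based tests.
make_spike_fixture <- function(events, duration, populations) {
  dbsnet:::new_spike_train_set(events, duration, 0.1, populations,
                               "fixture")
}
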