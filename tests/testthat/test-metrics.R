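test_that("attribution labels follow the peristimulus window rule", {
  pops <- list(thalamus = 2L)
  ev <- data.frame(population = "thalamus", neuron = c(1L, 1L, 2L),
                   time_ms = c(101, 210, 55), label = "unlabeled")
  sp <- make_spike_fixture(ev, 1000, pops)
  tr <- make_pulse_train(10, 180, 100, 0, 1000) # onsets 0, 100, ..., 900
  lab <- attribute_spikes(sp, tr, window = 3)
  expect_equal(lab$events$label,
               c("stimulus_locked", "background", "background"))
  # empty train: everything is background
  off <- attribute_spikes(sp, NULL)
  expect_true(all(off$events$label == "background"))
  # degenerate window rejected
  expect_error(attribute_spikes(sp, make_pulse_train(400, 180, 1, 0, 1000),
                                window = 3), "inter-pulse")
})

test_that("label counts are conserved exactly on a real run", {
  run <- cached_run_60()
  lab <- run$spikes$events$label
  expect_identical(sum(lab == "stimulus_locked") + sum(lab == "background"),
                   length(lab))
  m <- dbsnet:::run_metrics(run$spikes, run$train, burn_in = 500)
  # stim + background rates add up to the total rate, per population
  expect_equal(m$total_rate,
               m$stim_per_pulse * sum(run$train$onsets >= 500) / 1 +
                 m$background_rate)
})

test_that("per-pulse propagation counts a saturated fixture correctly", {
  pops <- list(cortex_exc = 400L)
  tr <- make_pulse_train(10, 180, 100, 0, 2000)
  onsets <- tr$onsets[tr$onsets >= 500]
  ev <- data.frame(population = "cortex_exc",
                   neuron = rep(1:400, times = length(onsets)),
                   time_ms = rep(onsets + 1, each = 400),
                   label = "unlabeled")
  sp <- attribute_spikes(make_spike_fixture(ev, 2000, pops), tr)
  expect_equal(per_pulse_propagation(sp, "cortex_exc", tr, burn_in = 500),
               400)
  expect_equal(background_propagation_rate(sp, "cortex_exc", 500), 0)
  expect_error(per_pulse_propagation(sp, "cortex_exc",
                                     make_pulse_train(10, 180, 1, 0, 400),
                                     burn_in = 500), "no pulses")
})

test_that("DBS-off background rate equals the total rate", {
  net <- cached_net()
  cfg <- simulation_config(duration = 1500, burn_in = 500, seed = 4)
  sp <- attribute_spikes(run_simulation(net, NULL, cfg), NULL)
  ev <- sp$events[sp$events$time_ms >= 500, ]
  for (pop in c("thalamus", "cortex_exc"))
    expect_equal(background_propagation_rate(sp, pop, 500),
                 sum(ev$population == pop) / 1)
})

test_that("a degenerate one-frequency one-seed sweep equals a single run", {
  net <- cached_net()
  cfg <- simulation_config(duration = 1500, burn_in = 500, seed = 1)
  sw <- frequency_sweep(net, frequencies = 60, seeds = 1, cfg = cfg,
                        amplitude = cached_amplitude())
  run <- cached_run_60()
  m <- dbsnet:::run_metrics(run$spikes, run$train, 500)
  expect_equal(sort(sw$entries$stim_per_pulse),
               sort(m$stim_per_pulse))
  expect_equal(sort(sw$entries$background_rate),
               sort(m$background_rate))
})

test_that("sweep input validation", {
  net <- cached_net()
  expect_error(frequency_sweep(net, frequencies = c(10, 10), seeds = 1),
               "increasing")
})

test_that("regime classification follows the threshold order", {
  mk <- function(thal, ce_bg, ce_spp, mo) {
    data.frame(population = c("thalamus", "cortex_exc", "cortex_inh",
                              "motor_out"),
               stim_per_pulse = c(NA, ce_spp, NA, NA),
               background_rate = c(thal, ce_bg, 0, mo),
               total_rate = c(thal, ce_bg, 0, mo))
  }
  base <- mk(8000, 6000, NA, 3000)
  # identical to baseline with zero stim-locked spikes: additive boundary
  eq <- mk(8000, 6000, 0, 3000)
  expect_identical(classify_regime(eq, base), "additive")
  # silent thalamus dominates every other label
  expect_identical(classify_regime(mk(0, 0, 10, 0), base), "silent")
  # suppressed background with cortex driven but output dead: blockade
  expect_identical(classify_regime(mk(8000, 10, 300, 10), base), "blockade")
  # suppressed background, cortex driven, output alive: substitution
  expect_identical(classify_regime(mk(8000, 10, 300, 3000), base),
                   "substitution")
  # nothing matches
  expect_identical(classify_regime(mk(8000, 2000, 0, 3000), base),
                   "indeterminate")
  expect_error(classify_regime(eq, mk(0, 0, NA, 0)), "baseline")
})

test_that("the calibrated network at 185 Hz is not in the additive regime", {
  sw <- cached_sweep()
  base <- sw$entries[sw$entries$frequency == 0, ]
  lab <- classify_regime(sw$entries[sw$entries$frequency == 185, ], base)
  expect_true(lab %in% c("blockade", "substitution"))
})
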