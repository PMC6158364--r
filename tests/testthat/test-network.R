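test_that("the default network has the four populations at their sizes", {
  net <- build_default_network(seed = 1)
  expect_equal(net$populations$name,
               c("thalamus", "cortex_exc", "cortex_inh", "motor_out"))
  expect_equal(net$populations$size, c(400L, 400L, 100L, 400L))
  expect_equal(net$populations$preset,
               c("thalamocortical", "regular_spiking", "fast_spiking",
                 "regular_spiking"))
  expect_equal(sum(net$populations$size), 1300L)
})

test_that("relay projections are the identity pairing and inhibition is diffuse", {
  net <- build_default_network(seed = 1)
  edges <- network_edges(net)
  tc <- edges[edges$pre_pop == "thalamus" & edges$post_pop == "cortex_exc", ]
  expect_equal(tc$pre_id, 1:400)
  expect_equal(tc$post_id, 1:400)
  cm <- edges[edges$pre_pop == "cortex_exc" & edges$post_pop == "motor_out", ]
  expect_equal(cm$pre_id, cm$post_id)
  # every interneuron reaches every output cell
  im <- edges[edges$pre_pop == "cortex_inh" & edges$post_pop == "motor_out", ]
  outdeg <- table(im$pre_id)
  expect_equal(as.vector(outdeg), rep(400L, 100L))
})

test_that("adjacency realization is deterministic and seed-dependent", {
  expect_identical(build_default_network(seed = 7),
                   build_default_network(seed = 7))
  n1 <- build_default_network(seed = 1)
  n2 <- build_default_network(seed = 2)
  expect_false(identical(n1$connections[[1]]$edges,
                         n2$connections[[1]]$edges))
})

test_that("random recurrent in-degree matches the binomial law within 3 sigma", {
  net <- build_default_network(seed = 11)
  for (k in c(1, 2, 4)) { # recurrent connections of the 400-size populations
    cn <- net$connections[[k]]
    n <- 400
    indeg <- tabulate(cn$edges[, 2], nbins = n)
    expected <- 0.1 * (n - 1)
    # the mean in-degree averages n binomial(n-1, 0.1) draws
    sem <- sqrt((n - 1) * 0.1 * 0.9 / n)
    expect_lt(abs(mean(indeg) - expected), 3 * sem)
    expect_false(any(cn$edges[, 1] == cn$edges[, 2])) # no self-edges
  }
})

test_that("edge weight signs follow the presynaptic role", {
  edges <- network_edges(build_default_network(seed = 1))
  inh <- edges$pre_pop == "cortex_inh"
  expect_true(all(edges$weight[inh] < 0))
  expect_true(all(edges$weight[!inh] > 0))
})

test_that("sustained-oscillation detection classifies constructed spike sets", {
  pops <- list(thalamus = 400L, cortex_exc = 400L, cortex_inh = 100L,
               motor_out = 400L)
  empty <- make_spike_fixture(
    data.frame(population = character(0), neuron = integer(0),
               time_ms = numeric(0), label = character(0)), 700, pops)
  expect_false(detect_sustained_oscillation(empty, 500, 200))

  # every thalamic neuron firing periodically at 10 Hz through the window
  times <- rep(seq(500, 700, by = 100), each = 400)
  periodic <- make_spike_fixture(
    data.frame(population = "thalamus", neuron = rep(1:400, 3),
               time_ms = times, label = "unlabeled"), 700, pops)
  expect_true(detect_sustained_oscillation(periodic, 500, 200))

  # a transient confined to the first 50 ms after offset
  transient <- make_spike_fixture(
    data.frame(population = "thalamus", neuron = 1:400,
               time_ms = runif(400, 500, 550), label = "unlabeled"),
    700, pops)
  expect_false(detect_sustained_oscillation(transient, 500, 200))

  expect_error(detect_sustained_oscillation(empty, 500, 50), "100 ms")
})

test_that("weight calibration satisfies both operational criteria", {
  net <- cached_net()
  expect_true(net$calibrated)
  # criterion (i): a synchronous thalamic volley drives the output layer
  exc <- dbsnet:::check_excitability(net, seed = 1)
  expect_gte(exc$motor_spikes, 50)
  # criterion (ii): activity dies out after the drive is switched off
  dec <- dbsnet:::check_decay(net, drive = default_drive(), seed = 1)
  expect_true(dec$pass)
})

test_that("calibration is reproducible under a fixed seed", {
  net2 <- calibrate_weights(build_default_network(seed = 1), seed = 1)
  net <- cached_net()
  expect_identical(c(net$g_E, net$g_I), c(net2$g_E, net2$g_I))
  expect_identical(net$calibration$motor_spikes_50ms,
                   net2$calibration$motor_spikes_50ms)
})

test_that("drive calibration lands the thalamic rate inside the band", {
  drive <- calibrate_drive(cached_net(), seed = 1)
  rate <- attr(drive, "thalamic_rate")
  expect_gte(rate, 10)
  expect_lte(rate, 40)
})
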