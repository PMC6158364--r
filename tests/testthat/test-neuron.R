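test_that("presets return the canonical parameter sets and reject unknown names", {
  rs <- make_preset("regular_spiking")
  expect_equal(unlist(rs), c(a = 0.02, b = 0.2, c = -65, d = 8, v_peak = 30))
  fs <- make_preset("fast_spiking")
  expect_equal(unlist(fs), c(a = 0.1, b = 0.2, c = -65, d = 2, v_peak = 30))
  tc <- make_preset("thalamocortical")
  expect_equal(unlist(tc),
               c(a = 0.02, b = 0.25, c = -65, d = 0.05, v_peak = 30))
  expect_error(make_preset("bursting"), "regular_spiking")
})

test_that("parameter validation enforces the model invariants", {
  expect_error(izh_params(a = 0, b = 0.2, c = -65, d = 8), "positive")
  expect_error(izh_params(a = 0.02, b = 0.2, c = 40, d = 8), "v_peak")
  expect_error(izh_params(a = NA, b = 0.2, c = -65, d = 8), "finite")
})

test_that("resting states match the quadratic closed form for all presets", {
  # independent oracle: roots of 0.04 v^2 + (5 - b) v + 140 = 0
  for (name in c("regular_spiking", "fast_spiking", "thalamocortical")) {
    p <- make_preset(name)
    v_star <- (-(5 - p$b) - sqrt((5 - p$b)^2 - 22.4)) / 0.08
    rs <- resting_state(p)
    expect_equal(rs$v, v_star, tolerance = 1e-9)
    expect_equal(rs$u, p$b * v_star, tolerance = 1e-9)
    # verify it really is an equilibrium by direct substitution
    expect_lt(abs(0.04 * rs$v^2 + 5 * rs$v + 140 - rs$u), 1e-9)
  }
  expect_equal(resting_state(make_preset("regular_spiking")),
               neuron_state(-70, -14))
  tc <- resting_state(make_preset("thalamocortical"))
  expect_equal(tc$v, -64.413911, tolerance = 1e-6)
  expect_equal(tc$u, -16.103478, tolerance = 1e-6)
})

test_that("resting state is rejected when the nullclines do not intersect", {
  # (5 - b)^2 < 22.4 has no real roots
  p <- izh_params(a = 0.02, b = 4.5, c = -65, d = 8)
  expect_error(resting_state(p), "discriminant")
})

test_that("the resting state is a numerical fixed point for every preset", {
  for (name in c("regular_spiking", "fast_spiking", "thalamocortical")) {
    p <- make_preset(name)
    s0 <- resting_state(p)
    s1 <- step_neuron(s0, p, I = 0, dt = 0.1)
    expect_false(s1$spiked)
    expect_lt(abs(s1$state$v - s0$v), 1e-6)
    expect_lt(abs(s1$state$u - s0$u), 1e-6)
  }
})

test_that("the reset rule is exact", {
  p <- make_preset("regular_spiking")
  u0 <- -10
  res <- step_neuron(neuron_state(30, u0), p, I = 0, dt = 0.1)
  expect_true(res$spiked)
  expect_identical(res$state$v, p$c)
  expect_identical(res$state$u, (u0 + p$a * (p$b * 30 - u0) * 0.1) + p$d)
})

test_that("sustained suprathreshold current elicits spiking within 50 ms", {
  # brute-force oracle at dt = 0.01 ms agrees with the default step
  p <- make_preset("regular_spiking")
  fine <- simulate_neuron(p, I = 10, duration = 50, dt = 0.01)
  expect_gt(length(fine$spike_times), 0)
  coarse <- simulate_neuron(p, I = 10, duration = 50, dt = 0.1)
  expect_gt(length(coarse$spike_times), 0)
})

test_that("halving dt changes spike times by less than 1 ms per spike", {
  p <- make_preset("regular_spiking")
  ref <- simulate_neuron(p, I = 10, duration = 500, dt = 0.01)$spike_times
  for (dt in c(0.1, 0.05)) {
    tr <- simulate_neuron(p, I = 10, duration = 500, dt = dt)$spike_times
    n <- min(length(tr), length(ref))
    expect_gt(n, 3)
    # timing drift accumulates linearly; the error per spike stays small
    expect_lt(max(abs(tr[1:n] - ref[1:n]) / seq_len(n)), 1)
  }
})

test_that("fast-spiking cells outrate regular-spiking cells at fixed drive", {
  rs <- simulate_neuron(make_preset("regular_spiking"), I = 10,
                        duration = 1000)
  fs <- simulate_neuron(make_preset("fast_spiking"), I = 10,
                        duration = 1000)
  expect_gt(length(fs$spike_times), length(rs$spike_times))
})

test_that("step_neuron validates its inputs", {
  p <- make_preset("regular_spiking")
  s <- resting_state(p)
  expect_error(step_neuron(s, p, I = Inf), "finite")
  expect_error(step_neuron(s, p, I = 0, dt = 0), "dt")
  expect_error(step_neuron(s, p, I = 0, dt = 1.5), "dt")
})
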