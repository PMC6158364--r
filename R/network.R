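#' Default synaptic base weights
#'
#' Per-projection base weights of the default network, in millivolts of
#' instantaneous depolarization delivered to the target per presynaptic
#' spike (delta synapses; see the package vignette for the rationale).
#' Signs follow the presynaptic role: excitatory positive, inhibitory
#' negative. The excitatory calibration scale `g_E` multiplies all
#' positive weights and `g_I` all negative weights (see
#' [calibrate_weights()]).
#'
#' The relay projections (`thalamus_to_cortex`, `cortex_to_output`) are
#' 1:1 and individually suprathreshold at unit scale, so cortex follows
#' its thalamic partner spike-for-spike with submillisecond latency.
#' Recurrent collaterals are weak (about `p * size` of them converge on
#' each cell and they must stay far subcritical or the population
#' synchronizes into runaway volleys). Fast-spiking interneurons are
#' recruited both by direct thalamic feedforward input and by cortical
#' activity, and their diffuse projection onto the output cells uses
#' slow (exponential-decay) kinetics, so inhibition accumulates across
#' pulses at short inter-pulse intervals and silences the output layer;
#' their within-cortex projection is fast (delta) and truncates
#' slow-rising cortical responses. See the package vignette for the
#' full rationale.
#'
#' @return Named list of base weights.
#' @export
default_base_weights <- function() {
  list(recurrent_exc     = 0.01,  # within thalamus, cortex_exc, motor_out
       recurrent_inh     = -0.5,  # within cortex_inh
       thalamus_to_cortex = 90,   # 1:1 relay, strongly suprathreshold
       thalamus_to_inh    = 2,    # thalamus -> cortex_inh, p = 0.1 (feedforward)
       cortex_to_output   = 36,   # 1:1 relay, moderately suprathreshold
       exc_to_inh         = 2,    # cortex_exc -> cortex_inh, p = 0.1
       inh_to_cortex      = -3,   # cortex_inh -> cortex_exc, p = 0.1
       inh_to_output      = -2)   # cortex_inh -> motor_out, all-to-all, slow
}

#' Default background drive
#'
#' Per-population constant bias current plus independent per-step
#' Gaussian noise, in model current units. Only thalamus is driven
#' directly by default ("intrinsic drive"); cortex and output are driven
#' trans-synaptically. The default is a mostly tonic bias with weak
#' noise, so relay cells fire quasi-regularly (~16 spikes/s, inside the
#' 10-40 band checked by [calibrate_drive()]); the low cycle-to-cycle
#' jitter is what gives the sharp frequency cutoff of background
#' propagation (see the package vignette).
#'
#' @return Named list with `bias` and `noise_sd`, each a named numeric
#'   vector keyed by population.
#' @export
default_drive <- function() {
  list(bias = c(thalamus = 0.85),
       noise_sd = c(thalamus = 0.3))
}

.pop_table <- function() {
  data.frame(
    name   = c("thalamus", "cortex_exc", "cortex_inh", "motor_out"),
    size   = c(400L, 400L, 100L, 400L),
    preset = c("thalamocortical", "regular_spiking", "fast_spiking",
               "regular_spiking"),
    role   = c("excitatory", "excitatory", "inhibitory", "excitatory"),
    stringsAsFactors = FALSE)
}

# Realize an edge list for one projection. Returns a 2-column integer
# matrix of (pre_id, post_id), 1-based within-population indices.
# Random topologies consume the current RNG stream.
realize_edges <- function(topology, n_pre, n_post, connect_prob,
                          same_pop = FALSE) {
  switch(topology,
    one_to_one = {
      if (n_pre != n_post)
        stop("one_to_one connection requires equal population sizes")
      cbind(pre = seq_len(n_pre), post = seq_len(n_post))
    },
    diffuse = {
      cbind(pre = rep(seq_len(n_pre), each = n_post),
            post = rep.int(seq_len(n_post), n_pre))
    },
    random_recurrent = {
      stopifnot(connect_prob > 0, connect_prob <= 1)
      hit <- which(stats::runif(n_pre * n_post) < connect_prob)
      pre <- ((hit - 1L) %/% n_post) + 1L
      post <- ((hit - 1L) %% n_post) + 1L
      keep <- !(same_pop & pre == post) # no self-edges
      cbind(pre = pre[keep], post = post[keep])
    },
    stop("unknown topology '", topology, "'"))
}

#' Build the default four-population network
#'
#' Constructs the thalamo-cortical-output circuit: 400 thalamocortical
#' relay neurons, 400 regular-spiking excitatory cortical neurons, 100
#' fast-spiking inhibitory cortical interneurons, and 400 regular-spiking
#' motor output neurons. Thalamus projects 1:1 onto excitatory cortex,
#' excitatory cortex projects 1:1 onto the output cells, inhibitory
#' cortex projects diffusely (all-to-all) onto the output cells and
#' randomly within cortex, thalamus and excitatory cortex both recruit
#' the interneurons through random connections (feedforward and
#' recurrent inhibition), and every population has sparse random
#' recurrent collaterals. Adjacency is realized deterministically from
#' the seed.
#'
#' All synapses deliver their weight as an instantaneous charge (delta
#' kinetics) except the inhibitory-to-output projection, which is an
#' exponential-decay current with time constant `tau_inh_ms`.
#'
#' @param seed RNG seed for adjacency realization.
#' @param connect_prob connection probability of the random projections.
#' @param weights base weight list, see [default_base_weights()].
#' @param delay_ms conduction delay applied to every projection.
#' @param tau_inh_ms decay time constant (ms) of the slow inhibitory
#'   current onto the output population.
#' @return An object of class `dbs_network` with unit calibration scales
#'   (`g_E = g_I = 1`, `calibrated = FALSE`).
#' @export
build_default_network <- function(seed = 1, connect_prob = 0.1,
                                  weights = default_base_weights(),
                                  delay_ms = 1, tau_inh_ms = 15) {
  pops <- .pop_table()
  set.seed(seed)
  conn <- function(pre, post, topology, weight, p = NA_real_,
                   kinetics = "delta") {
    n_pre <- pops$size[pops$name == pre]
    n_post <- pops$size[pops$name == post]
    role <- pops$role[pops$name == pre]
    if ((role == "excitatory" && weight <= 0) ||
        (role == "inhibitory" && weight >= 0))
      stop("weight sign of ", pre, " -> ", post,
           " must match the presynaptic role (", role, ")")
    list(pre = pre, post = post, topology = topology, weight = weight,
         connect_prob = p, delay = delay_ms, kinetics = kinetics,
         edges = realize_edges(topology, n_pre, n_post, p,
                               same_pop = identical(pre, post)))
  }
  connections <- list(
    conn("thalamus",   "thalamus",   "random_recurrent",
         weights$recurrent_exc, connect_prob),
    conn("cortex_exc", "cortex_exc", "random_recurrent",
         weights$recurrent_exc, connect_prob),
    conn("cortex_inh", "cortex_inh", "random_recurrent",
         weights$recurrent_inh, connect_prob),
    conn("motor_out",  "motor_out",  "random_recurrent",
         weights$recurrent_exc, connect_prob),
    conn("thalamus",   "cortex_exc", "one_to_one",
         weights$thalamus_to_cortex),
    conn("thalamus",   "cortex_inh", "random_recurrent",
         weights$thalamus_to_inh, connect_prob),
    conn("cortex_exc", "motor_out",  "one_to_one",
         weights$cortex_to_output),
    conn("cortex_exc", "cortex_inh", "random_recurrent",
         weights$exc_to_inh, connect_prob),
    conn("cortex_inh", "cortex_exc", "random_recurrent",
         weights$inh_to_cortex, connect_prob),
    conn("cortex_inh", "motor_out",  "diffuse",
         weights$inh_to_output, kinetics = "slow"))
  structure(list(populations = pops, connections = connections,
                 weights = weights, connect_prob = connect_prob,
                 delay_ms = delay_ms, tau_inh_ms = tau_inh_ms, seed = seed,
                 g_E = 1, g_I = 1, calibrated = FALSE,
                 calibration = NULL),
            class = "dbs_network")
}

#' @export
print.dbs_network <- function(x, ...) {
  cat("Thalamo-cortical-output DBS network\n")
  cat(sprintf("  populations: %s\n",
              paste(sprintf("%s (%d, %s)", x$populations$name,
                            x$populations$size, x$populations$preset),
                    collapse = ", ")))
  cat(sprintf("  %d projections, delay %g ms, seed %d\n",
              length(x$connections), x$delay_ms, x$seed))
  if (x$calibrated)
    cat(sprintf("  calibrated: g_E = %g, g_I = %g\n", x$g_E, x$g_I))
  else
    cat("  not calibrated\n")
  invisible(x)
}

#' Export realized adjacency as an edge data frame
#'
#' @param net a `dbs_network`.
#' @return Data frame with columns `pre_pop, pre_id, post_pop, post_id,
#'   weight, delay_ms`; weights include the calibration scales.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "dbs_network"))
  do.call(rbind, lapply(net$connections, function(cn) {
    g <- if (cn$weight > 0) net$g_E else net$g_I
    data.frame(pre_pop = cn$pre, pre_id = cn$edges[, 1],
               post_pop = cn$post, post_id = cn$edges[, 2],
               weight = cn$weight * g, delay_ms = cn$delay,
               stringsAsFactors = FALSE)
  }))
}

#' Detect sustained network oscillation after drive offset
#'
#' Operationalizes "prevent sustained oscillation": after all external
#' drive has ceased at `offset_time`, the network is considered to
#' oscillate if any population's mean firing rate over the last half of
#' the observation window exceeds 0.1 spikes/s/neuron.
#'
#' @param spikes a `spike_train_set` covering
#'   `[offset_time, offset_time + window]`.
#' @param offset_time time (ms) at which external drive ceased.
#' @param window observation window length (ms); at least 100.
#' @param rate_threshold sustained-activity threshold
#'   (spikes/s/neuron).
#' @return Logical flag.
#' @export
detect_sustained_oscillation <- function(spikes, offset_time, window,
                                         rate_threshold = 0.1) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (window < 100)
    stop("window must be at least 100 ms to assess sustained activity")
  lo <- offset_time + window / 2
  hi <- offset_time + window
  ev <- spikes$events
  ev <- ev[ev$time_ms > lo & ev$time_ms <= hi, , drop = FALSE]
  if (nrow(ev) == 0) return(FALSE)
  for (pop in names(spikes$populations)) {
    n <- sum(ev$population == pop)
    rate <- n / spikes$populations[[pop]] / ((hi - lo) / 1000)
    if (rate > rate_threshold) return(TRUE)
  }
  FALSE
}

#' Calibrate global connection-strength scales
#'
#' Grid search over a global excitatory scale `g_E` and inhibitory scale
#' `g_I` (each multiplying every weight of its sign), accepting the first
#' pair in lexicographic order that satisfies both operational criteria:
#'
#' * excitability: a single synchronous thalamic volley, with DBS and
#'   background drive off, elicits at least 50 motor-output spikes within
#'   50 ms;
#' * no sustained oscillation: after 500 ms of background drive is
#'   switched off, every population's rate falls below 0.1
#'   spikes/s/neuron within 200 ms ([detect_sustained_oscillation()]).
#'
#' @param net a `dbs_network`.
#' @param drive background drive, see [default_drive()].
#' @param seed RNG seed used for both test protocols.
#' @param g_E_grid,g_I_grid candidate scales, searched in lexicographic
#'   order (`g_E` outer).
#' @param dt integration step (ms).
#' @return The network with `g_E`, `g_I`, `calibrated = TRUE` and a
#'   `calibration` record. If no grid point satisfies both criteria, an
#'   error reports the near-misses (grid points satisfying exactly one
#'   criterion).
#' @export
calibrate_weights <- function(net, drive = default_drive(), seed = 1,
                              g_E_grid = c(0.5, 1, 2, 4, 8),
                              g_I_grid = c(1, 2, 4, 8, 16),
                              dt = 0.1) {
  stopifnot(inherits(net, "dbs_network"))
  trials <- list()
  for (gE in g_E_grid) {
    for (gI in g_I_grid) {
      cand <- net
      cand$g_E <- gE
      cand$g_I <- gI
      exc <- check_excitability(cand, seed = seed, dt = dt)
      dec <- check_decay(cand, drive = drive, seed = seed, dt = dt)
      trials[[length(trials) + 1L]] <-
        data.frame(g_E = gE, g_I = gI,
                   motor_spikes_50ms = exc$motor_spikes,
                   excitable = exc$pass, decays = dec$pass)
      if (exc$pass && dec$pass) {
        cand$calibrated <- TRUE
        cand$calibration <- list(
          seed = seed, drive = drive, dt = dt,
          motor_spikes_50ms = exc$motor_spikes,
          trials = do.call(rbind, trials))
        return(cand)
      }
    }
  }
  trials <- do.call(rbind, trials)
  near <- trials[xor(trials$excitable, trials$decays), , drop = FALSE]
  stop("calibration failed: no (g_E, g_I) on the grid satisfies both ",
       "criteria.\nNear-misses (one criterion met):\n",
       paste(utils::capture.output(print(near)), collapse = "\n"))
}

# Criterion (i): synchronous thalamic volley at t = 0 with drive and DBS
# off must elicit >= `min_spikes` motor_out spikes within `within_ms`.
check_excitability <- function(net, seed = 1, dt = 0.1,
                               within_ms = 50, min_spikes = 50) {
  cfg <- simulation_config(dt = dt, duration = within_ms + 10, burn_in = 0,
                           seed = seed,
                           drive = list(bias = numeric(0),
                                        noise_sd = numeric(0)))
  sp <- run_simulation(net, train = NULL, cfg = cfg, volley_time = 0)
  ev <- sp$events
  n <- sum(ev$population == "motor_out" & ev$time_ms <= within_ms)
  list(pass = n >= min_spikes, motor_spikes = n)
}

# Criterion (ii): with background drive on for `drive_ms` then switched
# off, all populations must be quiescent within `settle_ms`.
check_decay <- function(net, drive, seed = 1, dt = 0.1,
                        drive_ms = 500, settle_ms = 200) {
  cfg <- simulation_config(dt = dt, duration = drive_ms + settle_ms,
                           burn_in = 0, seed = seed, drive = drive,
                           drive_end = drive_ms)
  sp <- run_simulation(net, train = NULL, cfg = cfg)
  list(pass = !detect_sustained_oscillation(sp, drive_ms, settle_ms))
}

#' Calibrate the background drive
#'
#' Seeded grid search over the thalamic bias current (at fixed noise SD)
#' accepting the first bias for which the DBS-off thalamic firing rate
#' falls inside the target band.
#'
#' @param net a `dbs_network` (calibration scales as set).
#' @param band target thalamic rate band (spikes/s/neuron).
#' @param bias_grid candidate bias currents.
#' @param noise_sd per-step Gaussian noise SD.
#' @param seed RNG seed.
#' @param duration test duration (ms); rate measured after 500 ms
#'   burn-in.
#' @return A drive list as in [default_drive()], with the measured rate
#'   attached as attribute `thalamic_rate`.
#' @export
calibrate_drive <- function(net, band = c(10, 40),
                            bias_grid = seq(0.6, 2, by = 0.05),
                            noise_sd = 0.3, seed = 1, duration = 1500) {
  for (bias in bias_grid) {
    drive <- list(bias = c(thalamus = bias),
                  noise_sd = c(thalamus = noise_sd))
    cfg <- simulation_config(duration = duration, burn_in = 500,
                             seed = seed, drive = drive)
    sp <- run_simulation(net, train = NULL, cfg = cfg)
    ev <- sp$events
    n <- sum(ev$population == "thalamus" & ev$time_ms > cfg$burn_in)
    rate <- n / 400 / ((duration - cfg$burn_in) / 1000)
    if (rate >= band[1] && rate <= band[2]) {
      attr(drive, "thalamic_rate") <- rate
      return(drive)
    }
  }
  stop("no bias in the grid lands the thalamic rate in [",
       band[1], ", ", band[2], "] spikes/s/neuron")
}

#' Build and calibrate the default network
#'
#' Convenience wrapper: [build_default_network()] followed by
#' [calibrate_weights()] with the default drive.
#'
#' @param seed RNG seed for adjacency and calibration.
#' @param ... passed to [build_default_network()].
#' @return A calibrated `dbs_network`.
#' @export
calibrated_network <- function(seed = 1, ...) {
  calibrate_weights(build_default_network(seed = seed, ...), seed = seed)
}
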