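#' Simulation configuration
#'
#' @param dt integration step (ms), in (0, 1].
#' @param duration total simulated time (ms).
#' @param burn_in initial interval (ms) excluded from metrics; must be
#'   shorter than `duration`.
#' @param seed master RNG seed; fixes initial-state jitter and all
#'   background noise.
#' @param drive background drive, see [default_drive()].
#' @param drive_end time (ms) at which background drive switches off
#'   (`Inf` keeps it on throughout).
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(dt = 0.1, duration = 2000, burn_in = 500,
                              seed = 1, drive = default_drive(),
                              drive_end = Inf) {
  if (!(dt > 0 && dt <= 1)) stop("dt must lie in (0, 1] ms")
  if (burn_in >= duration) stop("burn_in must be shorter than duration")
  if (any(drive$noise_sd < 0)) stop("noise SD must be non-negative")
  structure(list(dt = dt, duration = duration, burn_in = burn_in,
                 seed = as.integer(seed), drive = drive,
                 drive_end = drive_end),
            class = "sim_config")
}

# Flatten population structure into global per-neuron parameter arrays.
# Global neuron order follows the population table; within a population,
# neurons are numbered 1..size.
flatten_network <- function(net) {
  pops <- net$populations
  offsets <- c(0L, cumsum(pops$size))[seq_len(nrow(pops))]
  names(offsets) <- pops$name
  N <- sum(pops$size)
  par <- matrix(0, N, 5,
                dimnames = list(NULL, c("a", "b", "c", "d", "v_peak")))
  for (k in seq_len(nrow(pops))) {
    p <- make_preset(pops$preset[k])
    idx <- offsets[k] + seq_len(pops$size[k])
    par[idx, ] <- matrix(c(p$a, p$b, p$c, p$d, p$v_peak),
                         pops$size[k], 5, byrow = TRUE)
  }
  # adjacency in CSR form keyed by global presynaptic index
  src <- integer(0); tgt <- integer(0); w <- numeric(0); kin <- integer(0)
  for (cn in net$connections) {
    g <- if (cn$weight > 0) net$g_E else net$g_I
    src <- c(src, offsets[cn$pre] + cn$edges[, 1])
    tgt <- c(tgt, offsets[cn$post] + cn$edges[, 2])
    w <- c(w, rep.int(cn$weight * g, nrow(cn$edges)))
    k <- if (identical(cn$kinetics, "slow")) 1L else 0L
    kin <- c(kin, rep.int(k, nrow(cn$edges)))
  }
  ord <- order(src, tgt)
  src <- src[ord]; tgt <- tgt[ord]; w <- w[ord]; kin <- kin[ord]
  ptr <- c(0L, cumsum(tabulate(src, nbins = N)))
  list(N = N, offsets = offsets, params = par,
       syn_ptr = as.integer(ptr), syn_tgt = as.integer(tgt - 1L),
       syn_w = w, syn_kin = kin)
}

# States along one period of the tonic firing limit cycle of a neuron
# under constant bias, sampled per integration step. Integration starts
# at rest and the first two cycles are discarded as transient.
limit_cycle_states <- function(params, bias, dt) {
  state <- resting_state(params)
  spikes_seen <- 0L
  cycle <- NULL
  for (k in seq_len(2e5)) {
    if (spikes_seen == 2L)
      cycle <- rbind(cycle, c(state$v, state$u))
    res <- step_neuron(state, params, bias, dt)
    state <- res$state
    if (res$spiked) {
      spikes_seen <- spikes_seen + 1L
      if (spikes_seen == 3L) return(cycle)
    }
  }
  NULL # subthreshold bias: no limit cycle
}

# Map global neuron indices back to (population, within-population id).
.global_to_pop <- function(idx, pops, offsets) {
  bin <- findInterval(idx - 1L, c(offsets, sum(pops$size)),
                      rightmost.closed = TRUE)
  list(population = pops$name[bin], neuron = idx - offsets[bin])
}

config_fingerprint <- function(net, cfg, train) {
  key <- list(populations = net$populations,
              weights = net$weights, connect_prob = net$connect_prob,
              delay_ms = net$delay_ms, net_seed = net$seed,
              g_E = net$g_E, g_I = net$g_I,
              dt = cfg$dt, duration = cfg$duration,
              burn_in = cfg$burn_in, seed = cfg$seed,
              drive = cfg$drive, drive_end = cfg$drive_end,
              train = if (is.null(train)) NULL else
                train[c("frequency", "pulse_width_us", "amplitude",
                        "t_start", "t_end")])
  fnv1a64(serialize(key, NULL, version = 3))
}

new_spike_train_set <- function(events, duration, dt, populations,
                                fingerprint = NA_character_) {
  structure(list(events = events, duration = duration, dt = dt,
                 populations = populations, fingerprint = fingerprint),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("Spike train set: %d events over %g ms, %d populations\n",
              nrow(x$events), x$duration, length(x$populations)))
  counts <- table(factor(x$events$population, levels = names(x$populations)))
  for (pop in names(x$populations))
    cat(sprintf("  %-10s %6d spikes (%.1f spikes/s/neuron)\n", pop,
                counts[[pop]],
                counts[[pop]] / x$populations[[pop]] / (x$duration / 1000)))
  cat("  fingerprint:", x$fingerprint, "\n")
  invisible(x)
}

#' Run the network simulation
#'
#' Time-stepped simulation of the full network: per-step background
#' drive (bias plus Gaussian noise, seeded), delayed delta-synaptic
#' delivery, DBS pulse current injected synchronously into all thalamic
#' neurons, and spike recording. Identical configuration and seed give a
#' bit-identical result.
#'
#' Undriven neurons start at the resting state of their preset with a
#' seeded uniform jitter of +/- 1 mV on `v` to break symmetry; tonically
#' driven populations start at seeded uniformly random phases of their
#' single-neuron firing cycle, so the population is asynchronous from
#' the outset.
#'
#' @param net a `dbs_network`.
#' @param train a [pulse_train] or `NULL` for DBS off; its epoch must lie
#'   within `[0, duration]`.
#' @param cfg a [simulation_config()].
#' @param volley_time if non-`NULL`, time (ms) at which every neuron of
#'   `volley_population` is forced to fire synchronously (used by the
#'   excitability calibration).
#' @param volley_population population receiving the forced volley.
#' @return A `spike_train_set`: time-sorted events
#'   (`population, neuron, time_ms, label`), all labeled `"unlabeled"`,
#'   plus the configuration fingerprint.
#' @export
run_simulation <- function(net, train = NULL, cfg = simulation_config(),
                           volley_time = NULL,
                           volley_population = "thalamus") {
  stopifnot(inherits(net, "dbs_network"), inherits(cfg, "sim_config"))
  if (!is.null(train) && (train$t_start < 0 || train$t_start > cfg$duration))
    stop("stimulus epoch must start within [0, duration]")
  fl <- flatten_network(net)
  n_steps <- as.integer(ceiling(cfg$duration / cfg$dt))

  pops <- net$populations
  bias <- numeric(fl$N)
  noise_sd <- numeric(fl$N)
  for (pop in names(cfg$drive$bias)) {
    idx <- fl$offsets[pop] + seq_len(pops$size[pops$name == pop])
    bias[idx] <- cfg$drive$bias[[pop]]
  }
  for (pop in names(cfg$drive$noise_sd)) {
    idx <- fl$offsets[pop] + seq_len(pops$size[pops$name == pop])
    noise_sd[idx] <- cfg$drive$noise_sd[[pop]]
  }
  drive_end_step <- if (is.finite(cfg$drive_end))
    as.integer(ceiling(cfg$drive_end / cfg$dt)) else n_steps

  stim_mask <- rep(FALSE, fl$N)
  stim_mask[fl$offsets["thalamus"] +
              seq_len(pops$size[pops$name == "thalamus"])] <- TRUE
  stim_current <- pulse_step_currents(train, n_steps, cfg$dt)

  volley_mask <- rep(FALSE, fl$N)
  volley_step <- -1L
  if (!is.null(volley_time)) {
    volley_step <- as.integer(round(volley_time / cfg$dt))
    idx <- fl$offsets[volley_population] +
      seq_len(pops$size[pops$name == volley_population])
    volley_mask[idx] <- TRUE
  }

  set.seed(cfg$seed)
  v0 <- u0 <- numeric(fl$N)
  driven <- names(cfg$drive$bias)[cfg$drive$bias > 0]
  for (k in seq_len(nrow(pops))) {
    p <- make_preset(pops$preset[k])
    rs <- resting_state(p)
    idx <- fl$offsets[k] + seq_len(pops$size[k])
    if (pops$name[k] %in% driven) {
      # tonically driven neurons sit on a firing limit cycle, not at
      # rest: start each neuron at a uniformly random phase of that
      # cycle so the population is asynchronous from the first step
      cyc <- limit_cycle_states(p, cfg$drive$bias[[pops$name[k]]], cfg$dt)
      if (is.null(cyc)) { # subthreshold bias: no cycle to randomize over
        v0[idx] <- rs$v + stats::runif(pops$size[k], -1, 1)
        u0[idx] <- rs$u
      } else {
        ph <- sample.int(nrow(cyc), pops$size[k], replace = TRUE)
        v0[idx] <- cyc[ph, 1]
        u0[idx] <- cyc[ph, 2]
      }
    } else {
      v0[idx] <- rs$v + stats::runif(pops$size[k], -1, 1)
      u0[idx] <- rs$u
    }
  }

  res <- sim_core(fl$params[, "a"], fl$params[, "b"], fl$params[, "c"],
                  fl$params[, "d"], fl$params[, "v_peak"],
                  v0, u0, fl$syn_ptr, fl$syn_tgt, fl$syn_w, fl$syn_kin,
                  n_steps, cfg$dt, bias, noise_sd, drive_end_step,
                  stim_current, stim_mask,
                  as.integer(ceiling(net$delay_ms / cfg$dt)),
                  volley_step, volley_mask, -90,
                  if (is.null(net$tau_inh_ms)) 15 else net$tau_inh_ms)

  loc <- .global_to_pop(res$neuron, pops, fl$offsets)
  events <- data.frame(population = loc$population,
                       neuron = as.integer(loc$neuron),
                       time_ms = round((res$step + 1) * cfg$dt, 9),
                       label = rep("unlabeled", length(res$step)),
                       stringsAsFactors = FALSE)
  sizes <- stats::setNames(as.integer(pops$size), pops$name)
  new_spike_train_set(events, cfg$duration, cfg$dt, as.list(sizes),
                      config_fingerprint(net, cfg, train))
}
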