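#' Attribute spikes to the stimulus or to background activity
#'
#' A spike at time `t` is labeled `stimulus_locked` if some pulse onset
#' `o` satisfies `o <= t < o + window`, and `background` otherwise. With
#' an empty train (DBS off) every spike is background. The window must
#' be shorter than the inter-pulse interval, so labels are unambiguous
#' and the stimulus takes precedence on the (measure-zero) overlap of a
#' window end with the next onset.
#'
#' @param spikes a `spike_train_set`.
#' @param train the [pulse_train] that was applied (or `NULL`).
#' @param window attribution window in ms after each pulse onset.
#' @return The spike set with every event labeled.
#' @export
attribute_spikes <- function(spikes, train = NULL, window = 3) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (window <= 0) stop("attribution window must be positive")
  ev <- spikes$events
  if (is.null(train) || length(train$onsets) == 0) {
    ev$label <- rep("background", nrow(ev))
  } else {
    if (train$frequency > 0 && window >= 1000 / train$frequency)
      stop("attribution window (", window, " ms) must be shorter than ",
           "the inter-pulse interval (",
           round(1000 / train$frequency, 3), " ms)")
    idx <- findInterval(ev$time_ms, train$onsets)
    o <- train$onsets[pmax(idx, 1L)]
    locked <- idx > 0 & ev$time_ms >= o & (ev$time_ms - o) < window
    ev$label <- ifelse(locked, "stimulus_locked", "background")
  }
  spikes$events <- ev
  spikes
}

.pop_counts <- function(ev, populations) {
  tab <- table(factor(ev$population, levels = names(populations)))
  as.numeric(tab)
}

#' Stimulus-locked spikes per pulse
#'
#' Count of stimulus-locked spikes in a population after burn-in,
#' divided by the number of pulses after burn-in (population aggregate;
#' divide by the population size for a per-neuron figure).
#'
#' @param labeled a labeled `spike_train_set` (see [attribute_spikes()]).
#' @param population population name.
#' @param train the applied [pulse_train].
#' @param burn_in interval (ms) excluded from the count.
#' @return Spikes per pulse (numeric scalar).
#' @export
per_pulse_propagation <- function(labeled, population, train,
                                  burn_in = 500) {
  stopifnot(inherits(labeled, "spike_train_set"))
  n_pulses <- sum(train$onsets >= burn_in)
  if (n_pulses == 0)
    stop("no pulses after burn-in; per-pulse propagation is undefined")
  ev <- labeled$events
  n <- sum(ev$population == population & ev$label == "stimulus_locked" &
             ev$time_ms >= burn_in)
  n / n_pulses
}

#' Background (non-stimulus-locked) firing rate
#'
#' Background-labeled spike count in a population after burn-in, divided
#' by the elapsed time in seconds.
#'
#' @inheritParams per_pulse_propagation
#' @return Spikes per second (population aggregate).
#' @export
background_propagation_rate <- function(labeled, population,
                                        burn_in = 500) {
  stopifnot(inherits(labeled, "spike_train_set"))
  elapsed <- labeled$duration - burn_in
  if (elapsed < 500)
    stop("at least 500 ms of post-burn-in data are required")
  ev <- labeled$events
  n <- sum(ev$population == population & ev$label == "background" &
             ev$time_ms >= burn_in)
  n / (elapsed / 1000)
}

# Per-population metrics of one labeled run at one frequency.
run_metrics <- function(labeled, train, burn_in) {
  pops <- names(labeled$populations)
  elapsed_s <- (labeled$duration - burn_in) / 1000
  ev <- labeled$events[labeled$events$time_ms >= burn_in, , drop = FALSE]
  do.call(rbind, lapply(pops, function(pop) {
    sel <- ev$population == pop
    n_locked <- sum(sel & ev$label == "stimulus_locked")
    n_bg <- sum(sel & ev$label == "background")
    n_pulses <- if (is.null(train)) 0L else sum(train$onsets >= burn_in)
    data.frame(population = pop,
               stim_per_pulse = if (n_pulses > 0) n_locked / n_pulses
                                else NA_real_,
               background_rate = n_bg / elapsed_s,
               total_rate = (n_locked + n_bg) / elapsed_s,
               stringsAsFactors = FALSE)
  }))
}

#' Frequency sweep
#'
#' Runs the simulation at every requested DBS frequency for every seed,
#' attributes spikes, and collects per-population propagation metrics.
#' Frequency 0 denotes a DBS-off baseline run (all spikes background,
#' per-pulse metrics undefined).
#'
#' @param net a calibrated `dbs_network`.
#' @param frequencies increasing vector of frequencies (Hz); see
#'   [default_sweep_frequencies()].
#' @param seeds one or more RNG seeds; entries are seed-averages.
#' @param cfg a [simulation_config()] (its seed is replaced per run).
#' @param window attribution window (ms).
#' @param amplitude pulse amplitude in model units; by default
#'   auto-calibrated from the thalamic preset
#'   ([calibrate_pulse_amplitude()]).
#' @param pulse_width_us pulse width (microseconds).
#' @return An object of class `sweep_result`: `entries` (seed-averaged
#'   per frequency x population), `per_seed` (every run), `seeds`,
#'   `frequencies`, and the configuration fingerprint of the network.
#' @export
frequency_sweep <- function(net, frequencies = default_sweep_frequencies(),
                            seeds = 1, cfg = simulation_config(),
                            window = 3, amplitude = NULL,
                            pulse_width_us = 180) {
  stopifnot(inherits(net, "dbs_network"), length(seeds) >= 1)
  if (is.unsorted(frequencies, strictly = TRUE))
    stop("frequencies must be strictly increasing")
  if (is.null(amplitude))
    amplitude <- calibrate_pulse_amplitude(make_preset("thalamocortical"),
                                           dt = cfg$dt,
                                           pulse_width_us = pulse_width_us)
  rows <- list()
  for (f in frequencies) {
    for (s in seeds) {
      train <- if (f > 0)
        make_pulse_train(f, pulse_width_us, amplitude,
                         t_start = 0, t_end = cfg$duration)
      else NULL
      run_cfg <- cfg
      run_cfg$seed <- as.integer(s)
      sp <- tryCatch(
        run_simulation(net, train = train, cfg = run_cfg),
        error = function(e)
          stop("sweep aborted at frequency ", f, " Hz, seed ", s, ": ",
               conditionMessage(e)))
      lab <- attribute_spikes(sp, train, window = window)
      m <- run_metrics(lab, train, run_cfg$burn_in)
      m$frequency <- f
      m$seed <- s
      rows[[length(rows) + 1L]] <- m
    }
  }
  per_seed <- do.call(rbind, rows)
  entries <- stats::aggregate(
    per_seed[c("stim_per_pulse", "background_rate", "total_rate")],
    by = per_seed[c("frequency", "population")],
    FUN = mean)
  entries <- entries[order(entries$frequency, entries$population), ]
  rownames(entries) <- NULL
  structure(list(entries = entries, per_seed = per_seed,
                 frequencies = frequencies, seeds = seeds,
                 window = window, amplitude = amplitude,
                 config_fingerprint =
                   config_fingerprint(net, cfg, NULL)),
            class = "sweep_result")
}

#' Default sweep frequency grid
#'
#' Spans the 5-250 Hz stimulation range and contains the three
#' raster-figure frequencies 10, 60 and 185 Hz.
#'
#' @return Numeric vector of frequencies (Hz).
#' @export
default_sweep_frequencies <- function() {
  c(5, 10, 20, 30, 40, 60, 80, 100, 125, 150, 185, 250)
}

#' Classify the qualitative propagation regime at one frequency
#'
#' Maps one frequency's metrics, relative to a DBS-off baseline from the
#' same network and seeds, onto a qualitative regime label:
#'
#' * `silent`: thalamic total rate below 5% of baseline;
#' * `blockade`: cortical background below 10% of baseline and motor
#'   output total rate below 10% of baseline;
#' * `substitution`: cortical background below 10% of baseline with
#'   stimulus-locked spikes present in cortex;
#' * `additive`: cortical background at or above 50% of baseline and
#'   stimulus-locked cortical activity either absent or above the
#'   chance-coincidence level (baseline rate x window);
#' * `indeterminate`: none of the above.
#'
#' The first matching label in the order silent, blockade, substitution,
#' additive wins. Thresholds are configurable.
#'
#' @param metrics one frequency's rows of a `sweep_result` `entries`
#'   data frame (all four populations).
#' @param baseline the frequency-0 rows from the same sweep.
#' @param thresholds named list: `silent` (default 0.05), `suppressed`
#'   (0.1), `additive` (0.5).
#' @param window attribution window (ms) used for the chance level.
#' @return A regime label (character scalar).
#' @export
classify_regime <- function(metrics, baseline,
                            thresholds = list(silent = 0.05,
                                              suppressed = 0.1,
                                              additive = 0.5),
                            window = 3) {
  g <- function(df, pop, col) df[df$population == pop, col][1]
  base_thal <- g(baseline, "thalamus", "total_rate")
  base_ce_bg <- g(baseline, "cortex_exc", "background_rate")
  base_mo <- g(baseline, "motor_out", "total_rate")
  if (any(c(base_thal, base_ce_bg, base_mo) == 0))
    stop("baseline rates of zero: cannot normalize regime thresholds")
  thal <- g(metrics, "thalamus", "total_rate")
  ce_bg <- g(metrics, "cortex_exc", "background_rate")
  ce_spp <- g(metrics, "cortex_exc", "stim_per_pulse")
  mo <- g(metrics, "motor_out", "total_rate")
  if (thal < thresholds$silent * base_thal) return("silent")
  if (ce_bg < thresholds$suppressed * base_ce_bg) {
    if (mo < thresholds$suppressed * base_mo) return("blockade")
    if (!is.na(ce_spp) && ce_spp > 0) return("substitution")
  }
  if (ce_bg >= thresholds$additive * base_ce_bg) {
    chance <- base_ce_bg * window / 1000
    if (is.na(ce_spp) || ce_spp == 0 || ce_spp > chance) return("additive")
  }
  "indeterminate"
}
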