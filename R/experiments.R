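#' Default experiment configuration
#'
#' Nested configuration driving the command-line experiments. Every run
#' writes its fully resolved configuration as JSON beside its outputs,
#' so any artifact is reproducible from the sibling JSON alone.
#'
#' @param seed master seed (adjacency, calibration and simulation).
#' @return Nested list of class `experiment_config`.
#' @export
experiment_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    network = list(connect_prob = 0.1,
                   weights = default_base_weights(),
                   delay_ms = 1),
    simulation = list(dt = 0.1, duration_ms = 2000, burn_in_ms = 500,
                      drive = default_drive()),
    dbs = list(frequency_hz = 130, pulse_width_us = 180,
               amplitude_mode = "clinical_auto", amplitude_value = 1.5,
               t_start_ms = 0, t_end_ms = NA),
    attribution = list(window_ms = 3),
    sweep = list(frequencies_hz = default_sweep_frequencies(),
                 seeds = 1:3),
    fig4 = list(frequencies_hz = c(10, 60, 185)),
    output = list(dir = ".", figures = TRUE)),
    class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Keys present in the file override the defaults of
#' [experiment_config()]; absent keys keep their default.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_into <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge_into(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  cfg <- merge_into(unclass(experiment_config()), user)
  structure(cfg, class = "experiment_config")
}

write_resolved_config <- function(config, path, extra = list()) {
  out <- c(unclass(config), extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# Rejected before any simulation starts so a long run cannot fail at
# the write stage.
ensure_output_dir <- function(out_dir) {
  if (!dir.exists(out_dir))
    suppressWarnings(dir.create(out_dir, recursive = TRUE))
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0)
    stop("output directory '", out_dir, "' is not writable")
  out_dir
}

# Instantiate network, drive and simulation config from an experiment
# config; calibrates weights and, in clinical_auto mode, the pulse
# amplitude.
setup_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  net <- build_default_network(seed = config$seed,
                               connect_prob = config$network$connect_prob,
                               weights = config$network$weights,
                               delay_ms = config$network$delay_ms)
  net <- calibrate_weights(net, drive = config$simulation$drive,
                           seed = config$seed)
  sim <- config$simulation
  cfg <- simulation_config(dt = sim$dt, duration = sim$duration_ms,
                           burn_in = sim$burn_in_ms, seed = config$seed,
                           drive = sim$drive)
  amplitude <- if (identical(config$dbs$amplitude_mode, "model_units"))
    config$dbs$amplitude_value
  else
    calibrate_pulse_amplitude(make_preset("thalamocortical"), dt = sim$dt,
                              pulse_width_us = config$dbs$pulse_width_us)
  list(net = net, cfg = cfg, amplitude = amplitude)
}

#' Raster plot of a simulation
#'
#' One row per neuron, grouped by population in the order thalamus,
#' cortex_inh, cortex_exc, motor_out (thalamus at the top), one colour
#' per population.
#'
#' @param spikes a `spike_train_set`.
#' @param order population display order (top to bottom).
#' @param colors one colour per displayed population.
#' @param main plot title.
#' @export
plot_raster <- function(spikes,
                        order = c("thalamus", "cortex_inh", "cortex_exc",
                                  "motor_out"),
                        colors = c(thalamus = "blue", cortex_inh = "red",
                                   cortex_exc = "darkgreen",
                                   motor_out = "black"),
                        main = "") {
  stopifnot(inherits(spikes, "spike_train_set"))
  sizes <- vapply(order, function(p) spikes$populations[[p]], 1L)
  tops <- cumsum(sizes)
  base <- c(0L, tops[-length(tops)])
  names(base) <- order
  total <- sum(sizes)
  graphics::plot(NULL, xlim = c(0, spikes$duration), ylim = c(total, 0),
                 xlab = "time (ms)", ylab = "neuron", main = main,
                 yaxs = "i", xaxs = "i")
  ev <- spikes$events[spikes$events$population %in% order, ]
  y <- base[ev$population] + ev$neuron
  graphics::points(ev$time_ms, y, pch = ".", col = colors[ev$population])
  graphics::abline(h = tops[-length(tops)], col = "grey70")
  invisible(NULL)
}

#' Frequency-response curves of a sweep
#'
#' Two panels: stimulus-locked spikes per pulse versus frequency, and
#' background firing versus frequency, per population.
#'
#' @param sweep a `sweep_result`.
#' @param which `"stim_per_pulse"`, `"background_rate"` or both.
#' @export
plot_sweep <- function(sweep,
                       which = c("stim_per_pulse", "background_rate")) {
  stopifnot(inherits(sweep, "sweep_result"))
  df <- sweep$entries[sweep$entries$frequency > 0, ]
  pops <- unique(df$population)
  cols <- c(thalamus = "blue", cortex_inh = "red",
            cortex_exc = "darkgreen", motor_out = "black")
  labels <- c(stim_per_pulse = "stimulus-locked spikes per pulse",
              background_rate = "background spikes/s")
  old <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (metric in which) {
    ylim <- range(df[[metric]], na.rm = TRUE)
    graphics::plot(NULL, xlim = range(df$frequency), ylim = ylim,
                   xlab = "DBS frequency (Hz)", ylab = labels[[metric]])
    for (pop in pops) {
      d <- df[df$population == pop, ]
      graphics::lines(d$frequency, d[[metric]], col = cols[[pop]], type = "b",
                      pch = 16)
    }
    graphics::legend("topright", legend = pops, col = cols[pops], lty = 1,
                     pch = 16, cex = 0.8, bty = "n")
  }
  invisible(NULL)
}

#' Reproduce the raster experiment
#'
#' Simulates the calibrated network at each configured frequency
#' (default 10, 60 and 185 Hz), writing one spike CSV and (optionally)
#' one raster figure per frequency, plus one resolved-config JSON.
#'
#' @param config an [experiment_config()].
#' @return Invisibly, a named list of `spike_train_set`s keyed by
#'   frequency.
#' @export
run_fig4 <- function(config = experiment_config()) {
  out_dir <- ensure_output_dir(config$output$dir)
  exp <- setup_experiment(config)
  runs <- list()
  for (f in config$fig4$frequencies_hz) {
    train <- make_pulse_train(f, config$dbs$pulse_width_us, exp$amplitude,
                              t_start = 0, t_end = exp$cfg$duration)
    sp <- run_simulation(exp$net, train, exp$cfg)
    sp <- attribute_spikes(sp, train, config$attribution$window_ms)
    write_spikes(sp, file.path(out_dir, sprintf("raster_%ghz.csv", f)))
    if (isTRUE(config$output$figures)) {
      grDevices::png(file.path(out_dir, sprintf("raster_%ghz.png", f)),
                     width = 1200, height = 800)
      plot_raster(sp, main = sprintf("DBS at %g Hz", f))
      grDevices::dev.off()
    }
    runs[[as.character(f)]] <- sp
  }
  write_resolved_config(config, file.path(out_dir, "fig4_config.json"),
                        extra = list(amplitude_model = exp$amplitude,
                                     g_E = exp$net$g_E, g_I = exp$net$g_I))
  invisible(runs)
}

#' Run the frequency-sweep experiment
#'
#' Executes [frequency_sweep()] over the configured grid (plus a DBS-off
#' baseline at frequency 0), writes the per-seed sweep CSV, a JSON
#' summary with per-frequency regime labels, and (optionally) the two
#' frequency-response figures.
#'
#' @param config an [experiment_config()].
#' @return Invisibly, the `sweep_result`.
#' @export
run_sweep <- function(config = experiment_config()) {
  out_dir <- ensure_output_dir(config$output$dir)
  exp <- setup_experiment(config)
  freqs <- sort(unique(c(0, config$sweep$frequencies_hz)))
  sweep <- frequency_sweep(exp$net, frequencies = freqs,
                           seeds = config$sweep$seeds, cfg = exp$cfg,
                           window = config$attribution$window_ms,
                           amplitude = exp$amplitude,
                           pulse_width_us = config$dbs$pulse_width_us)
  write_sweep(sweep, file.path(out_dir, "sweep.csv"))
  baseline <- sweep$entries[sweep$entries$frequency == 0, ]
  regimes <- vapply(setdiff(freqs, 0), function(f)
    classify_regime(sweep$entries[sweep$entries$frequency == f, ],
                    baseline), "")
  summary <- list(frequencies_hz = setdiff(freqs, 0), regimes = regimes,
                  amplitude_model = sweep$amplitude,
                  g_E = exp$net$g_E, g_I = exp$net$g_I)
  jsonlite::write_json(summary, file.path(out_dir, "sweep_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (isTRUE(config$output$figures)) {
    grDevices::png(file.path(out_dir, "sweep_stim_per_pulse.png"),
                   width = 900, height = 600)
    plot_sweep(sweep, "stim_per_pulse")
    grDevices::dev.off()
    grDevices::png(file.path(out_dir, "sweep_background.png"),
                   width = 900, height = 600)
    plot_sweep(sweep, "background_rate")
    grDevices::dev.off()
  }
  write_resolved_config(config, file.path(out_dir, "sweep_config.json"),
                        extra = list(amplitude_model = sweep$amplitude,
                                     g_E = exp$net$g_E, g_I = exp$net$g_I))
  invisible(sweep)
}
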