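#' Write spike events to CSV
#'
#' Writes the documented spike schema (`population, neuron, time_ms,
#' label`), preceded by a `#`-prefixed metadata line carrying the
#' configuration fingerprint, duration, time step and population sizes,
#' so a file round-trips losslessly through [read_spikes()].
#'
#' @param spikes a `spike_train_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train_set"))
  meta <- sprintf("# dbsnet_spikes fingerprint=%s duration_ms=%s dt=%s pops=%s",
                  spikes$fingerprint,
                  format(spikes$duration), format(spikes$dt),
                  paste(sprintf("%s:%d", names(spikes$populations),
                                unlist(spikes$populations)),
                        collapse = ","))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(spikes$events, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spike events from CSV
#'
#' Reads a file written by [write_spikes()] (or any CSV with the same
#' column schema; metadata then defaults from the data). Malformed rows
#' are rejected with their line numbers.
#'
#' @param path input file path.
#' @return A `spike_train_set`.
#' @export
read_spikes <- function(path) {
  first <- readLines(path, n = 1)
  meta <- list(fingerprint = NA_character_, duration = NA_real_,
               dt = NA_real_, pops = NULL)
  has_meta <- length(first) == 1 && startsWith(first, "# dbsnet_spikes")
  if (has_meta) {
    fields <- strsplit(sub("^# dbsnet_spikes ", "", first), " ")[[1]]
    kv <- strsplit(fields, "=")
    for (p in kv) {
      switch(p[1],
        fingerprint = meta$fingerprint <- p[2],
        duration_ms = meta$duration <- as.numeric(p[2]),
        dt = meta$dt <- as.numeric(p[2]),
        pops = {
          items <- strsplit(strsplit(p[2], ",")[[1]], ":")
          meta$pops <- stats::setNames(
            lapply(items, function(x) as.integer(x[2])),
            vapply(items, `[`, "", 1))
        })
    }
  }
  raw <- utils::read.csv(path, comment.char = "#",
                         colClasses = "character")
  required <- c("population", "neuron", "time_ms", "label")
  if (!identical(names(raw), required))
    stop("spike CSV must have columns ", paste(required, collapse = ", "))
  offset <- 1L + as.integer(has_meta) # header + optional metadata line
  ev <- data.frame(population = raw$population,
                   neuron = suppressWarnings(as.integer(raw$neuron)),
                   time_ms = suppressWarnings(as.numeric(raw$time_ms)),
                   label = raw$label,
                   stringsAsFactors = FALSE)
  bad <- which(is.na(ev$neuron) | is.na(ev$time_ms) | ev$time_ms < 0 |
                 ev$neuron < 1)
  if (length(bad))
    stop("malformed spike rows at line(s) ",
         paste(bad + offset, collapse = ", "),
         " (negative time, missing or non-positive neuron index)")
  if (is.null(meta$pops) && nrow(ev))
    meta$pops <- as.list(tapply(ev$neuron, ev$population, function(x)
      as.integer(max(x))))
  if (is.na(meta$duration))
    meta$duration <- if (nrow(ev)) max(ev$time_ms) else 0
  if (nrow(ev) && length(meta$pops)) {
    bad_idx <- which(mapply(function(pop, id)
      !is.null(meta$pops[[pop]]) && id > meta$pops[[pop]],
      ev$population, ev$neuron))
    if (length(bad_idx))
      stop("neuron index exceeds population size at line(s) ",
           paste(bad_idx + offset, collapse = ", "))
  }
  new_spike_train_set(ev, meta$duration, meta$dt, meta$pops,
                      meta$fingerprint)
}

#' Write sweep results to CSV
#'
#' Writes the per-seed sweep schema (`frequency_hz, population,
#' stim_per_pulse, background_rate_hz, total_rate_hz, seed`).
#'
#' @param sweep a `sweep_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  df <- sweep$per_seed
  out <- data.frame(frequency_hz = df$frequency,
                    population = df$population,
                    stim_per_pulse = df$stim_per_pulse,
                    background_rate_hz = df$background_rate,
                    total_rate_hz = df$total_rate,
                    seed = df$seed)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
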