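#' Izhikevich neuron parameter set
#'
#' Constructs and validates the five parameters of the two-variable
#' Izhikevich neuron model, `dv/dt = 0.04 v^2 + 5 v + 140 - u + I`,
#' `du/dt = a (b v - u)`, with reset `v <- c`, `u <- u + d` whenever `v`
#' reaches `v_peak`.
#'
#' @param a recovery time scale (1/ms); must be positive.
#' @param b recovery sensitivity (dimensionless).
#' @param c post-spike reset voltage (mV).
#' @param d post-spike recovery increment (model units).
#' @param v_peak spike cutoff voltage (mV); defaults to the conventional
#'   30 mV.
#' @return An object of class `izh_params`.
#' @seealso [make_preset()] for the named parameter sets used by the
#'   network model.
#' @export
izh_params <- function(a, b, c, d, v_peak = 30) {
  vals <- c(a = a, b = b, c = c, d = d, v_peak = v_peak)
  if (!all(is.finite(vals)))
    stop("all Izhikevich parameters must be finite")
  if (a <= 0)
    stop("recovery time scale 'a' must be positive")
  if (v_peak <= c)
    stop("spike cutoff 'v_peak' must exceed the reset voltage 'c'")
  structure(as.list(vals), class = "izh_params")
}

#' @export
print.izh_params <- function(x, ...) {
  cat(sprintf("Izhikevich parameters: a=%g b=%g c=%g d=%g v_peak=%g\n",
              x$a, x$b, x$c, x$d, x$v_peak))
  invisible(x)
}

.izh_presets <- list(
  regular_spiking  = list(a = 0.02, b = 0.2,  c = -65, d = 8),
  fast_spiking     = list(a = 0.1,  b = 0.2,  c = -65, d = 2),
  thalamocortical  = list(a = 0.02, b = 0.25, c = -65, d = 0.05)
)

#' Named Izhikevich parameter presets
#'
#' Returns the canonical published parameter sets for the three firing
#' phenotypes used in the network: cortical regular-spiking (RS)
#' excitatory cells, cortical fast-spiking (FS) inhibitory interneurons,
#' and thalamocortical (TC) relay cells.
#'
#' @param name one of `"regular_spiking"`, `"fast_spiking"`,
#'   `"thalamocortical"`.
#' @return An [izh_params] object.
#' @examples
#' make_preset("thalamocortical")
#' @export
make_preset <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.izh_presets))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid presets: ",
         paste(names(.izh_presets), collapse = ", "))
  p <- .izh_presets[[name]]
  izh_params(p$a, p$b, p$c, p$d)
}

#' Neuron state
#'
#' @param v membrane potential (mV).
#' @param u recovery variable (model units).
#' @return An object of class `neuron_state`.
#' @export
neuron_state <- function(v, u) {
  if (!is.finite(v) || !is.finite(u))
    stop("neuron state must be finite")
  structure(list(v = v, u = u), class = "neuron_state")
}

#' Analytic resting state of an Izhikevich neuron
#'
#' Solves the nullcline system at zero input: `u = b v` substituted into
#' `0.04 v^2 + 5 v + 140 - u = 0` gives the quadratic
#' `0.04 v^2 + (5 - b) v + 140 = 0`. The lower root is the stable
#' equilibrium; the upper root is the firing threshold of the
#' instantaneous dynamics.
#'
#' @param params an [izh_params] object.
#' @return A [neuron_state] at the stable equilibrium.
#' @examples
#' resting_state(make_preset("regular_spiking"))  # v = -70, u = -14
#' @export
resting_state <- function(params) {
  stopifnot(inherits(params, "izh_params"))
  disc <- (5 - params$b)^2 - 4 * 0.04 * 140
  if (disc < 0)
    stop("no resting state: nullcline discriminant is negative for b = ",
         params$b)
  v <- (-(5 - params$b) - sqrt(disc)) / (2 * 0.04)
  neuron_state(v = v, u = params$b * v)
}

#' Advance one neuron by one time step
#'
#' Forward-Euler update of the Izhikevich equations: one full step for
#' both `v` and `u` (the `u` update uses the pre-step `v`), spike
#' detection against `v_peak` on the updated `v`, and the hard reset
#' applied in the same step.
#'
#' @param state a [neuron_state].
#' @param params an [izh_params].
#' @param I input current (model units) held constant over the step.
#' @param dt time step in ms, in (0, 1].
#' @return A list with elements `state` (the post-step [neuron_state])
#'   and `spiked` (logical).
#' @export
step_neuron <- function(state, params, I, dt = 0.1) {
  stopifnot(inherits(state, "neuron_state"), inherits(params, "izh_params"))
  if (!is.finite(I))
    stop("non-finite input current (integration blow-up?)")
  if (!(dt > 0 && dt <= 1))
    stop("dt must lie in (0, 1] ms")
  v <- state$v
  u <- state$u
  vn <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + I)
  un <- u + dt * params$a * (params$b * v - u)
  if (!is.finite(vn) || !is.finite(un))
    stop("non-finite state after step (integration blow-up)")
  spiked <- vn >= params$v_peak
  if (spiked) {
    vn <- params$c
    un <- un + params$d
  }
  list(state = neuron_state(vn, un), spiked = spiked)
}

#' Simulate a single neuron under a current waveform
#'
#' Plain-R reference integrator used for pulse-threshold calibration and
#' for convergence checks of the compiled network engine. `I` may be a
#' single number (constant current) or a function of time (ms) returning
#' the current for the step starting at that time.
#'
#' @param params an [izh_params].
#' @param I constant current or `function(t)` in model units.
#' @param duration total simulated time (ms).
#' @param dt time step (ms).
#' @param state initial [neuron_state]; defaults to the resting state.
#' @return A list with `spike_times` (ms, spike at the end of its step)
#'   and the final `state`.
#' @export
simulate_neuron <- function(params, I, duration, dt = 0.1,
                            state = resting_state(params)) {
  n_steps <- ceiling(duration / dt)
  I_fun <- if (is.function(I)) I else function(t) I
  spikes <- numeric(0)
  for (k in seq_len(n_steps) - 1L) {
    res <- step_neuron(state, params, I_fun(k * dt), dt)
    state <- res$state
    if (res$spiked) spikes <- c(spikes, (k + 1) * dt)
  }
  list(spike_times = spikes, state = state)
}
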