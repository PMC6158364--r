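---
title: "Frequency response of a thalamo-cortical circuit to deep brain stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency response of a thalamo-cortical circuit to deep brain stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the model is for

Deep brain stimulation delivers a continuous train of brief current
pulses to a deep target — here, motor thalamus. Clinically its effect is
strongly frequency dependent, and a long-standing puzzle is how a
stimulus that *adds* activity can act like a lesion. `dbsnet` implements
a deliberately minimal population model of one proposed answer:

* each pulse discharges the whole target synchronously, so at high
  rates the stimulus *substitutes* its own rhythm for the endogenous
  (e.g. dystonic) pattern — the target fires at the stimulus frequency
  and carries no other information;
* the massively synchronous volleys that do propagate recruit
  feedforward and recurrent inhibition so effectively that, after a
  build-up period, nothing reaches the motor output — the stimulus
  pattern itself is behaviourally inert.

The package quantifies both effects by attributing every spike either
to the stimulus (within a short peristimulus window) or to background
activity, and sweeping stimulation frequency from 5 to 250 Hz.

## Circuit and dynamics

Neurons follow the two-variable Izhikevich model (quadratic voltage
`v`, slow recovery `u`, hard reset at 30 mV), integrated by forward
Euler with a single full step for `v` and `u` per `dt = 0.1` ms; the
`u` update uses the pre-step `v`, and reset is applied within the
detecting step. The default step resolves the 180 µs stimulation pulse
(two steps, charge-conserving quantization: full amplitude then 0.8 of
it). A membrane floor at -90 mV guards the quadratic equation, which is
not a valid membrane model far below rest and would otherwise rebound
unphysically under strong hyperpolarization.

Four populations (sizes 400/400/100/400) use the canonical published
parameter sets: thalamocortical relay cells (a = 0.02, b = 0.25,
c = -65, d = 0.05), regular-spiking excitatory cortex and motor output
(0.02, 0.2, -65, 8), and fast-spiking inhibitory interneurons (0.1,
0.2, -65, 2). Presets can be overridden through the experiment
configuration.

Projections (all with a 1 ms conduction delay, snapped up to the grid):

| projection | topology | base weight | kinetics |
|---|---|---|---|
| thalamus → cortex_exc | 1:1 | +90 | delta |
| cortex_exc → motor_out | 1:1 | +36 | delta |
| thalamus → cortex_inh | random, p = 0.1 | +2 | delta |
| cortex_exc → cortex_inh | random, p = 0.1 | +2 | delta |
| cortex_inh → cortex_exc | random, p = 0.1 | -3 | delta |
| cortex_inh → motor_out | all-to-all | -2 | slow (τ = 15 ms) |
| within-population collaterals | random, p = 0.1 | +0.01 / -0.5 | delta |

Weights are *delivered charge*: a delta synapse adds its weight, in mV,
to the target's membrane potential one delay after the presynaptic
spike (implemented as a one-step current `w/dt`). The slow inhibitory
projection instead feeds an exponential-decay current whose integrated
charge equals the weight. Two global scales, `g_E` over all excitatory
and `g_I` over all inhibitory weights, are the calibration handles.

## Why the circuit is tuned the way it is

The design space here is tightly constrained, and several defaults are
consequences rather than free choices:

**Relay synapses are strongly suprathreshold.** The raster phenomenology
requires cortex to follow its thalamic partner spike-for-spike at every
stimulation frequency. A relay EPSP near threshold fails twice over:
spike latency diverges near the saddle-node of the quadratic dynamics,
so marginal responses arrive 3–8 ms after the pulse and fall outside
any reasonable attribution window; and cortical adaptation (`d = 8` per
spike) raises `u` at high rates until the response collapses entirely.
At +90 mV the relay volley lands far above the saddle for every
reachable adaptation level, so the cortical response is submillisecond
at 5 Hz and at 250 Hz alike, and the lock-or-silent dichotomy that the
attribution window assumes is exact.

**Recurrent collaterals are almost negligible.** With ~40 collateral
inputs converging on each cell, any per-edge weight strong enough to
matter makes a synchronous volley self-regenerating (the population
refires every delay period indefinitely), violating the "no sustained
oscillation" calibration criterion; and even weak coupling between
near-identical regular oscillators synchronizes the thalamus into
deterministic population waves within a second, which destroys the
stationarity that the sham-stimulation chance-level control relies on.
The collaterals are therefore kept at a token +0.01 mV — present, but
dynamically silent.

**Inhibition onto the output is slow.** With uniform 1 ms delays, the
disynaptic inhibitory volley always arrives one delay after the
monosynaptic excitation it is meant to veto, so instantaneous
inhibition can never block the output per-pulse, no matter how strong.
Blocking that *builds up* — strong after several pulses at short
inter-pulse intervals, absent for a lone volley — requires inhibitory
current that outlasts a volley. The exponential time constant of 15 ms
makes the inhibitory current accumulate for inter-pulse intervals
shorter than a few tens of ms: output cells are held 10–15 mV below
rest at 60 Hz and above (complete blockade), recover fully between
pulses at 20 Hz and below (output follows), and a single test volley
passes through before the current has any effect — which is exactly the
calibration excitability criterion.

**Interneurons get direct thalamic feedforward input.** The fast delta
projection from the interneurons onto cortex truncates any cortical
response that has not completed within ~1 ms of the inhibitory volley.
Driven only through cortex, that volley would arrive too late to matter;
driven directly by the thalamic relay volley it arrives inside the
3 ms attribution window, which both sharpens cortical locking and
eliminates late stragglers that would otherwise be mislabeled as
background. Feedforward recruitment of fast-spiking cells is also the
canonical cortical circuit motif.

**Thalamic drive is tonic and quasi-regular.** The background
("endogenous") activity is generated by a constant bias current with
weak per-step Gaussian noise (`default_drive()`: bias 0.85, noise SD
0.3 in model units, thalamus only), giving each relay cell a ~16 spikes/s
intrinsic rhythm with ~5% cycle-to-cycle jitter. This is what produces
a sharp substitution cutoff: every stimulus volley resets the relay
cells' firing cycle, so background spikes only occur when the
inter-pulse interval exceeds the intrinsic period. With strongly
stochastic drive (high coefficient of variation) there is no sharp
cutoff — background leaks through at every frequency — and the
characteristic "no propagation beyond ~20 Hz" figure cannot arise.
Driven populations are initialized at uniformly random phases of their
single-neuron firing limit cycle; initializing uniformly in voltage
instead leaves the whole population phase-coherent for seconds.

## Calibration procedures

`calibrate_weights()` performs the seeded lexicographic grid search
over `g_E` ∈ {0.5, 1, 2, 4, 8} and `g_I` ∈ {1, 2, 4, 8, 16}, accepting
the first pair that satisfies both operational criteria: (i) a single
synchronous thalamic volley, with drive and DBS off, elicits at least
50 motor-output spikes within 50 ms; (ii) after 500 ms of background
drive is switched off, every population falls below 0.1 spikes/s/neuron
within 200 ms. On the default network the search accepts
`g_E = g_I = 1` (the base weights were chosen so that unit scales are
the calibrated operating point), and the full volley — 400 output
spikes — passes criterion (i).

`calibrate_pulse_amplitude()` maps the clinical "1.5 mA, 180 µs,
current mode" setting into model units without an electrode model:
bisection finds the smallest amplitude whose single pulse fires a
resting relay cell within 3 ms (~60 model units), and four times that
threshold is returned (~242). The suprathreshold multiple is the
package's stand-in for the fact that clinical current-mode stimulation
recruits axons well above threshold; at 4× the relay volley latency is
submillisecond, at 2× it is 1–1.5 ms, which consumes half of the
attribution window and visibly distorts downstream latencies.

`calibrate_drive()` checks the remaining free scalar: the thalamic bias
is accepted when the DBS-off relay rate lands in the 10–40
spikes/s/neuron band.

## Attribution and the frequency sweep

A spike at time `t` is stimulus-locked iff some pulse onset `o`
satisfies `o ≤ t < o + window`, with `window = 3` ms by default; the
window must be shorter than the inter-pulse interval (at 250 Hz the
interval is 4 ms, so 3 ms remains valid over the whole default sweep
{5, 10, 20, 30, 40, 60, 80, 100, 125, 150, 185, 250} Hz). Counts are
conserved by construction: stimulus-locked plus background equals
total, as exact integers.

A zero-amplitude (sham) train provides the chance-level control: its
onsets exist but inject nothing, so stimulus-locked counts are pure
coincidence and must equal `rate × window` per pulse for a stationary
process — this is asserted against simulation in the test suite.

`frequency_sweep()` runs every frequency × seed combination (default
3 seeds, 2 s per run with a 500 ms burn-in discarded from all metrics),
and `classify_regime()` maps each frequency onto a qualitative label
relative to the DBS-off baseline: `additive` (background ≥ 50% of
baseline), `substitution` (cortical background < 10% of baseline with
stimulus-locked cortex), `blockade` (additionally motor output < 10% of
baseline), `silent` (thalamus < 5% of baseline), evaluated in the order
silent → blockade → substitution → additive. On the default network the
sweep labels 5–10 Hz additive, 20–30 Hz substitution, and 40 Hz upward
blockade.

## What the defaults reproduce

With the defaults above (2 s per run, 3 seeds):

* background propagation into excitatory cortex declines monotonically
  with frequency and is exactly zero at every sweep frequency above
  20 Hz — substitution with a cutoff just above 20 Hz;
* stimulus-locked spikes per pulse in the thalamic target are flat-to-
  declining from 60 to 250 Hz (the window captures slightly more
  rebound activity at low frequency);
* cortex follows every pulse across the sweep, while stimulus-locked
  motor output is exactly zero at 60 Hz and above;
* at 10 Hz motor output carries several thousand background spikes/s —
  endogenous activity passes through between pulses.

## Numerical choices and degenerate inputs

* `dt = 0.1` ms default; halving it changes single-neuron spike times
  by far less than 1 ms per spike against a `dt = 0.01` ms reference.
* Pulse charge is conserved under `dt` refinement to 1e-9 by
  overlap-weighted quantization.
* Frequency 0 yields an empty train: all spikes are background, and
  per-pulse metrics are undefined (`NA`).
* Identical seeds give bit-identical spike trains, CSV files and
  calibration outcomes; every run is fingerprinted (FNV-1a over the
  serialized configuration) and the fingerprint survives CSV
  round-trips.
* Numeric blow-up (non-finite state) aborts with the offending step and
  neuron; the -90 mV floor prevents the quadratic rebound pathology.

## Problem sizes

The shipped experiments use 2 s of simulated time per frequency and
three seeds per condition — enough that the zero/non-zero distinctions
above are stable across seeds, while a full 13-frequency sweep
(including the DBS-off baseline) completes in about half a minute on a
single CPU. Longer runs sharpen the low-frequency background estimates
but do not change any qualitative outcome.

## Limitations

* No plasticity of any kind (synaptic or homeostatic) and no
  inhibitory output nucleus: the model addresses stimulation of
  thalamus with excitatory output to cortex, not pallidal stimulation.
* No electrode or tissue biophysics: "amplitude" is anchored to the
  neuron model by the suprathreshold calibration, not to milliamps.
* Delta/exponential point synapses and uniform 1 ms delays; no
  conductances, no distance-dependent connectivity.
* The relay chain is deliberately strong and reliable; the model is a
  demonstration of the substitution/blockade mechanism, not a fitted
  model of any particular patient's circuit. Real background activity
  is neither as regular nor as unit-rate-uniform as the tonic drive
  used here, so passing the packaged checks demonstrates the mechanism
  under idealized conditions rather than quantitative agreement with
  recordings.
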