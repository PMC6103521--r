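---
title: "Models and methods behind resonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind resonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`resonet` simulates a cortical output layer of excitatory principal cells
(PC) receiving strong feedback inhibition from fast-spiking interneurons
(IN), and quantifies how the network responds to asynchronous versus
rhythmic spike-train inputs.  This vignette explains the models, the
parameters that matter, the numerical choices, and what the package's
synthetic inputs do and do not emulate.

## The network and its assumptions

The control configuration is 20 two-compartment PCs and 5 INs, all-to-all
coupled: PC→IN by AMPA kinetics (maximal conductance 1 mS/cm², τ_r = 0.4
ms, τ_d = 2 ms, E = 0 mV) and IN→PC by perisomatic GABA_A (0.1 mS/cm²,
τ_d = 5 ms, E = −75 mV).  There are no PC–PC or IN–IN synapses, no
conduction delays, and no feedforward inhibition; connectivity is
deterministic all-to-all.  Block conductances are normalized by the total
number of afferents of the same type onto the target population, so (i)
scaling the populations up at fixed synaptic strength leaves the dynamics
unchanged (`control_network(n_pc = 100, n_in = 37)` behaves like the
control), and (ii) in the two-pathway competition network the shared IN
pool receives the same total AMPA conductance as in the single-pathway
control.  The GABA_A decay constant is the duration of feedback inhibition
and, together with the PCs' post-spike refractory dynamics, paces the
network rhythm.

## Cell models: an authored kinetics registry

The source publication for the cell biophysics specifies the currents by
name only; their rate functions are not printed.  The package therefore
ships its own, fully documented kinetics registry (`pc_kinetics()`,
`in_kinetics()`), designed to the same functional description and
calibrated against behavioural gates rather than copied constants:

* the isolated PC is regular spiking, with a subthreshold resonance of the
  voltage-fluctuation amplitude near 2 Hz under weak sinusoidal Poisson
  drive (0.1 kHz) and a spiking resonance at the same frequency at
  slightly suprathreshold drive (0.3 kHz);
* a dendritic AMPA drive of g_inp = 0.0015 mS/cm² at 1000 sp/s elicits
  somatic spiking;
* the IN is fast spiking with a higher maximal sustained rate than the PC;
* the control network converts asynchronous 1000 sp/s drive into a
  beta-band natural rhythm (> 15 Hz).

The PC soma carries RTM-style NaF/KDR spike currents whose kinetics are
shifted 12 mV depolarized (`naf_shift`, `kdr_shift`), leaving a
high-resistance, window-current-free subthreshold range; a persistent
sodium current (NaP, half-activation −52 mV, slope 10) amplifies
subthreshold inputs; a slow M-type potassium current (Ks, half-activation
−50 mV, slope 7, τ ≈ 70–150 ms) provides both the ~2 Hz resonant feedback
and a slow brake on sustained depolarization.  A high-threshold calcium
current (half-activation −20 mV) is effectively spike-gated; it feeds a
first-order calcium pool (τ_Ca = 14 ms) whose saturating KCa current
(`z = ca/(ca + kd)`, kd = 10) produces a hold-then-release
afterhyperpolarization.  That release wall, together with GABA_A decay,
sets the post-volley refractory period and hence the natural frequency and
the highest input frequency the network can relay cycle-for-cycle.  The
soma/dendrite area fraction (`p_soma = 0.4`) and coupling (`g_c = 0.15
mS/cm²`) were chosen so that dendritic inputs drive somatic spiking at the
calibrated rheobase.  The IN uses Wang–Buzsáki-style kinetics
(hyperpolarized activation, fast sodium inactivation) — a standard
fast-spiking model.  Every constant can be overridden
(`pc_kinetics(g_Ks = 0.03)`), and knockouts zero one named conductance
(`pc_cell(knockout = "Ks")`).

Two design choices deserve emphasis.  First, calcium in this registry
serves only to gate the KCa brake; removing it disinhibits the cell rather
than silencing it, which reverses one knockout direction relative to the
reference biophysics (see Limitations).  Second, the background-noise
coupling for the conductance-based network is not printed anywhere; the
package defaults to `g_noise = 0.004 mS/cm²`, the value at which the
control network expresses a stable beta-band natural rhythm while the
single-cell experiments (run without background) keep their calibrated
rheobase.  Both are configurable.

## Synthetic inputs: what they emulate

`rate_program()` builds the deterministic instantaneous rate λ(t) of an
upstream source population in one of three dynamical states: asynchronous
(constant λ = r_inp), sinusoidal, or square-wave modulated.  Square waves
emit periodic pulse packets: pulse width δ_inp encodes the synchrony of
the source (1 ms high, 10 ms medium, 19 ms low), and holding the
time-averaged rate fixed means lower frequencies deliver larger pulses —
as expected if slower rhythms arise in larger source pools.  The
fixed-amplitude variant instead holds the pulse height r_p fixed, so its
mean strength grows as r_p · f_inp · δ_inp.  `draw_poisson_spikes()`
realizes independent inhomogeneous Poisson trains per target cell by
thinning on the integration grid (at most one spike per 0.01 ms bin;
occupancy probability λ·dt ≪ 1 for all rates used), with per-source RNG
streams derived from one master seed so rasters are bit-reproducible.
Background activity is the superposition-equivalent aggregate of 100
uncorrelated 1 sp/s cells per PC.

The sine formula raises a normalization ambiguity: written as
λ = r_inp (1 + sin 2πf t)/2 its time average is r_inp/2, while the
symbol r_inp elsewhere denotes the time-averaged rate and "equal-strength"
comparisons assume matched means.  Both conventions are implemented
(`sine_mean = "matched"` / `"half"`); network sweeps default to matched
means (so sine, square, and asynchronous drives at the same r_inp are
equal-strength), while the single-cell ladder uses the printed half-mean
form, under which 0.1 kHz is subthreshold and 0.3 kHz slightly
suprathreshold for the calibrated cell.

What the generator does *not* emulate: correlated (non-Poisson) input
statistics, conduction delays, short-term plasticity, and any feedback
from the simulated network onto its sources.  Tests passing on these
inputs therefore say nothing about, e.g., bursty or oscillator-coupled
afferents beyond rate modulation.

## Numerical choices

Integration is fixed-step RK4 at dt = 0.01 ms; exogenous input gates are
exact exponential decays updated per step and held piecewise-constant
within a step.  Halving dt changes mean rates by far less than 2% and
leaves the population frequency in the same spectral bin (asserted in the
test suite).  Spikes are upward crossings of 0 mV at the soma with a 2 ms
minimum inter-detection interval; LIF cells use a grid-aligned
event-based update (reset and 3 ms hold) sharing the same input machinery.
Voltage traces are stored decimated at 0.1 ms; rasters at full
resolution.  Initial conditions are rest with ±1 mV per-cell uniform
jitter (configurable); the first 500 ms after signal onset are excluded
from analysis.  Trials abort with a diagnostic if any |V| exceeds 200 mV.

The iFR is a sum of unit-mass Gaussian kernels over population spike
times divided by the population size (kernel SD 6 ms for display, 2 ms
for spectra; an FWHM convention is available).  Welch spectra use Hann
windows, mean removal, 50% overlap, 1024-sample segments at 1 kHz
sampling (zero-padded when the analysis window is shorter), giving ≤ 1 Hz
bin spacing; the search band is 5–100 Hz and ties break toward the lower
frequency.  A trial is flagged as a nested-oscillation regime — and
excluded from population-frequency resonance extraction — when the
spectrum has a secondary local peak of at least half the primary power
and the primary lies above 1.5× the driving frequency; both thresholds
are arguments.  The natural frequency is the median f_pop across
asynchronous-drive realizations.

The LIF threshold deserves a note: with the printed leak (0.1 mS/cm²,
rest −65 mV) and input couplings, the subthreshold drive saturates about
10 mV above rest, so a 0 mV threshold can never be crossed.  The package
reads 0 mV as the spike-detection level and defaults the dynamical
threshold to −58 mV, at which the LIF network produces a ~20 Hz natural
rhythm and pulse-locked responses; `lif_params()` documents the override.

## Problem sizes

The full protocol (1–50 Hz in 1 Hz steps, 10 realizations, 2.5 s trials)
is available through `sweep_spec()` but is deliberately not the default
anywhere.  The test suite and the acceptance script use the desk-scale
protocols: 2 Hz grids over 16–32 Hz (rate resonance) and 20–36 Hz
(population-frequency resonance) with 2 realizations of 1.5 s trials;
1–10 Hz with 3 seeds of 2.9 s trials for the single-cell ladder; and 4 Hz
grids with 2 realizations for the property checks.  These sizes keep a
full run in minutes on one CPU while leaving the extracted argmax
frequencies within one grid step of their full-protocol values in our
spot checks.

## Known limitations

* The PC firing-rate profile of the control network under strong drive is
  flat to gently declining across 16–32 Hz rather than sharply peaked:
  per-pulse recruitment saturates below full participation at the fixed
  input coupling, so the firing-rate resonant frequency extracted at desk
  scale wobbles between 16 and 24 Hz depending on the seed, while the
  population-frequency resonance (locking cliff) is expressed robustly.
* Knockout directions reflect the authored registry, not the unpublished
  reference kinetics: removing Ks raises (weakly) the resonant frequency
  as expected, but removing Ca disinhibits rather than silences the PCs,
  and the NaP knockout shifts the flat rate profile's argmax upward.
* Asynchronously driven PCs in the competition network carry a small
  positive suppression-index baseline (~0.1) from the shared IN pool's
  load; the resonant-target condition is asserted against that baseline,
  not against zero.
* Only regular-spiking PCs and fast-spiking INs are modelled; no NMDA,
  probabilistic connectivity, PC–PC/IN–IN coupling, or plasticity.
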