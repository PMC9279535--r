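---
title: "Modeling steady-state entrainment in log-normal spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling steady-state entrainment in log-normal spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Cortical steady-state responses — entrainment of population activity to a
sustained periodic stimulus, measured electrophysiologically as the auditory
steady-state response (ASSR) or steady-state visually evoked potential — are
degraded in several psychiatric conditions, and excitation–inhibition (E/I)
imbalance is a leading candidate mechanism. `assrnet` implements an in-silico
version of this question: a recurrent spiking network whose
excitatory-to-excitatory (EE) synapses follow the heavy-tailed (log-normal)
amplitude distribution observed in cortex is driven by a periodic stimulus,
and the fidelity of entrainment is quantified by the power spectral density
(PSD) and the inter-trial phase coherence (ITPC) of the excitatory
population rate, across E/I ratios from 3:1 to 9:1 and with or without the
rare strong (> 9 mV) synapses of the distribution's tail.

## The model

Each neuron is a conductance-based leaky integrate-and-fire unit,

$$\frac{dv}{dt} = -\frac{1}{\tau_m}(v - V_L) - g_E (v - V_E)
  - g_I (v - V_I) + I_{ex},$$

with threshold/reset (spike when $v \ge V_{thr}$, reset to $V_r$, 1 ms
absolute refractory period) and first-order synaptic conductances

$$\frac{dg_X}{dt} = -\frac{g_X}{\tau_s}
  + \sum_j G_{X,j} \sum_{s_j} \delta(t - s_j - d_j), \qquad X \in \{E, I\}.$$

Parameters (units mV, ms): $V_L = -70$, $V_E = 0$, $V_I = -80$, $V_r = -60$,
$V_{thr} = -50$; $\tau_m = 20$ (excitatory) or $10$ (inhibitory);
$\tau_s = 2$ for both conductances. Integration is forward Euler at
$\Delta t = 0.1$ ms.

**Connectivity.** Directed Erdős–Rényi: every ordered pair is connected
independently with the outgoing probability of the presynaptic class — 0.1
for excitatory sources, 0.5 for inhibitory — with no self-connections and at
most one synapse per ordered pair. Delays are uniform on [1, 3] ms for EE
synapses and [0, 2] ms otherwise. The network holds 12000 neurons at
publication scale, split by the E/I ratio.

**Synaptic weights.** EE amplitudes $V_{EPSP}$ are drawn from the log-normal
density with $\sigma = 1$ and mode 0.2 mV (so $\mu = \log 0.2 + \sigma^2$,
taking the natural logarithm, consistent with the $\mu, \sigma$ scale of the
density); draws above 20 mV are rejected and redrawn. The conductance weight
is $G_{EE} = V_{EPSP}/100$, a calibration whose accuracy the package itself
checks: integrating the two-ODE single-synapse system
(`calibrate_single_epsp()`) shows the rule stays within about 8% of the true
peak depolarization over $V_{EPSP} \in [0.1, 10]$ mV — a small-amplitude
overshoot that saturation near threshold progressively cancels. Non-EE
weights are fixed: $G_{EI} = 0.018$, $G_{IE} = 0.002$, $G_{II} = 0.0025$
(conductance per ms). EE deliveries fail independently per spike with
$P_E = a/(a + V_{EPSP})$, $a = 0.1$ mV: weak synapses are unreliable, strong
ones nearly reliable. "Strong" synapses are those with $V_{EPSP} > 9$ mV;
the ablated condition deletes them (it does not resample below the cutoff),
matching the interpretation of removing each neuron's maximum-EPSP synapse.
With the printed parameters the expected number of strong synapses per
excitatory neuron at publication scale is about 0.4 (quadrature of the tail
mass times the expected EE out-degree); the package reports the measured
count rather than forcing a nominal value.

**Stimulus.** The external input is a windowed Poisson process: within a
1 ms window at the start of each period $1/F_s$, events arrive at
$\Lambda = 1$ Hz; outside the windows the rate is zero. Each event adds
21 mV to the membrane instantaneously, which exceeds the 20 mV gap from rest
to threshold, so an event arriving at rest always evokes a spike; the
directly evoked rate per neuron is $F_s \Lambda / 10^3$ Hz. The nominal
frequencies 40, 83.3, 90.9 and 142.8 Hz are realized exactly as integer
periods 25, 12, 11 and 7 ms, and all analysis uses the exact frequency
$1000/\mathrm{period}$. Every neuron, inhibitory ones included, is eligible
for stimulation (the membrane equation applies the external drive to the
generic neuron); `generate_stimulus()` can be restricted to a subset by
stimulating only the first $n$ ids.

## Evaluation indices

The excitatory population rate is
$r_E(t) = 1000\, S_E(t) / (\Delta t\, N_E)$ Hz with $S_E$ the per-bin spike
count, smoothed by a Gaussian kernel of $\sigma = 10$ ms (the membrane
time-constant scale). The smoothed rate over the analysis window [3, 7] s is
z-scored and analyzed by:

- **PSD**: a plain rectangular-window periodogram of the full 4 s segment
  (0.25 Hz resolution), one-sided, normalized so the powers sum to the
  window's mean square (exactly 1 after z-scoring). Trial averaging is done
  across the condition's 10 trials.
- **ITPC**: $\mathrm{ITPC}(T, f) = \bigl| \tfrac{1}{T} \sum_{m=1}^{T}
  F_m(f)/|F_m(f)| \bigr|$, the mean resultant length of the per-trial phase
  angles on the same single-segment Fourier grid as the PSD. Using one grid
  for both indices makes their band means directly comparable.
- **Band means**: arithmetic means over the grid frequencies in the closed
  interval $[F_s - \Delta f_s, F_s + \Delta f_s]$, $\Delta f_s \in \{1, 2,
  3\}$ Hz.

The seeding discipline is what gives the ITPC meaning: within a condition
the stimulus realization is pinned across trials, while topology, EPSP
amplitudes, delays, initial membrane potentials and transmission failures
are reseeded per trial. `stream_seed()` derives a named stream for each of
these from one master seed.

## Numerical choices

- **Per-step update order**: (1) conductance decay, (2) arriving synaptic
  increments, (3) stimulus jumps, (4) Euler voltage update, (5)
  threshold/reset and delivery scheduling. The continuous equations do not
  fix this order; this one makes the single-event spike guarantee exact
  (21 mV at rest leaves the membrane above threshold after the same step's
  leak update).
- **Delta inputs** are realized as instantaneous increments ($g \mathrel{+}= G$,
  $v \mathrel{+}= 21$), the exact integral of the delta under Euler.
- **Refractoriness** clamps the membrane at $V_r$ for 1 ms while
  conductances continue to decay and accumulate; stimulus jumps arriving in
  that window are lost (applying them to a clamped variable would discard
  them anyway; the choice is flagged because the model leaves it open).
- **Delays** are structural: drawn once per synapse as continuous uniforms,
  rounded to the grid at scheduling, and floored at one step so a delivery
  never lands in the step that produced it.
- **z-scoring** divides by the population (n-denominator) standard
  deviation, making the window's mean square exactly 1 and the Parseval
  identity of the periodogram exact to rounding. The [3, 7] s window is the
  half-open interval [3000, 7000) ms: exactly 40000 samples and a rational
  0.25 Hz grid.
- **Smoothing edges**: the truncated ($\pm 4\sigma$) unit-mass kernel is
  renormalized by its in-range mass near the series edges, so constant
  inputs are preserved exactly. The analysis window sits far from the
  edges.
- **Zero Fourier coefficients** carry no phase; such trial/frequency cells
  are excluded from the ITPC average with a warning (NA if every trial is
  excluded, as at the DC bin of a z-scored series). This only affects
  degenerate inputs such as noiseless sinusoid fixtures.
- **Error signalling**: a silent analysis window raises a classed
  degenerate-input error; `run_condition()` records such trials as
  `"degenerate"` and summarizes the rest. Divergence of the state raises an
  integration error carrying the failure time and aborts the condition with
  the trial index.
- **ITPC error bars**: ITPC is a cross-trial statistic with no per-trial
  value, so the reported `sd_itpc` is the spread of leave-one-trial-out
  band means (jackknife); band-power `sd` is the ordinary sample SD across
  trials.

## The synthetic fixtures, and what tests do and do not show

`make_phase_jittered_trials()` produces sinusoidal "rate" trials whose
phases are von Mises distributed with concentration $\kappa$; the expected
ITPC at the target frequency is the closed-form mean resultant length
$I_1(\kappa)/I_0(\kappa)$, which makes the whole ITPC pipeline testable
against an analytic law without any simulation.
`make_inhomogeneous_poisson_spikes()` generates spike records with a
prescribed rate profile by thinning, exercising the rate/smoothing/PSD
chain end to end. These fixtures emulate phase-locked periodic signals with
controlled jitter and Poisson sampling noise; they do not emulate recurrent
dynamics, refractory correlations, or the bistability discussed next, so
passing analysis tests validates the measurement chain, not the network
dynamics.

`scaled_preset(scale)` shrinks the 12000-neuron publication configuration
while preserving coupling probabilities and weights, so synaptic in-degree
shrinks proportionally. This has a qualitative consequence worth stating
plainly: the network is bistable between silence and a fluctuation-driven
active state, and the active state only exists at sufficient in-degree. At
full scale the 40 Hz stimulus ignites sustained irregular activity (about
2 Hz excitatory rate at E/I 4:1 over the analysis window); at scale 0.25
and below no ratio ignites, responses are purely stimulus-evoked, and —
because the stimulus is pinned across trials — trials are essentially
identical, driving the ITPC to 1.0 at every frequency. Scaled-down runs
therefore demonstrate the machinery and perfect locking, but the
competition between autonomous activity and entrainment that
differentiates conditions exists only near publication scale, which is why
quantitative claims about the E/I sweep are asserted only at `scale = 1`.

## Problem sizes

The test suite runs desk-scale checks: micro-circuits of 1–3 neurons for
engine oracles, networks of 100–2000 neurons for statistical recovery, one
full-scale (12000-neuron, 7 s) trial for the activity-regime check, and a
1200-neuron, 10-trial condition for the end-to-end smoke test. The
acceptance script recomputes the ITPC identity on 10 duplicated 4 s trials
and recovers $\Lambda$ from 2000 uncoupled neurons stimulated for 50 s
(about 4000 evoked spikes, i.e. a Monte-Carlo standard error of about
1.6%). The full publication grid (7 ratios x 4 frequencies x 2 synapse
settings x 10 trials at 12000 neurons) is available through
`run_ei_sweep(template = scaled_preset(1))` and is a multi-hour single-core
computation.

## Known limitations

Only local recurrent dynamics are modeled: no inter-regional connectivity,
no voltage-dependent (NMDA-like) currents, shared $\tau_s$ for excitation
and inhibition, and only the population-count route to E/I imbalance
(inhibitory conductance amplitude is held fixed). The stimulus is strictly
periodic windowed-Poisson; amplitude-modulated or naturalistic inputs are
out of scope. Ignition of the active state from the stimulus is stochastic
and seed-dependent near threshold ratios, so per-seed variability of sweep
summaries at intermediate scales is expected.
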