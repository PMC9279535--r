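# assrnet

Steady-state responses in spiking networks with log-normal synaptic
weights.

`assrnet` is for computational neuroscientists studying how
excitation–inhibition (E/I) balance shapes the entrainment of cortical
population activity to periodic stimuli — the mechanism behind the
auditory steady-state response (ASSR) and its degradation in psychiatric
conditions. The package simulates a recurrent network of conductance-based
leaky integrate-and-fire neurons whose excitatory-to-excitatory synapses
carry EPSP amplitudes from a truncated log-normal distribution (the
heavy-tailed weight statistics of cortex), drives it with a periodic
windowed-Poisson stimulus, and quantifies entrainment by power spectral
density and inter-trial phase coherence (ITPC).

## The model in brief

Membrane dynamics per neuron:

$$\dot v = -\tfrac{1}{\tau_m}(v - V_L) - g_E(v - V_E) - g_I(v - V_I) + I_{ex},
\qquad \dot g_X = -g_X/\tau_s + \textstyle\sum_j G_{X,j} \sum_{s_j} \delta(t - s_j - d_j),$$

with threshold $-50$ mV, reset $-60$ mV, 1 ms refractory period, forward
Euler at $\Delta t = 0.1$ ms. EE amplitudes follow
$p(x) = \exp[-(\log x - \mu)^2/2\sigma^2] / (\sqrt{2\pi}\,\sigma x)$ with
$\sigma = 1$, mode 0.2 mV, truncated at 20 mV; weights are
$G_{EE} = V_{EPSP}/100$ and deliveries fail with probability
$P_E = a/(a + V_{EPSP})$, $a = 0.1$ mV. The stimulus delivers 21 mV
membrane jumps from a Poisson process ($\Lambda = 1$ Hz) gated to a 1 ms
window per period. Entrainment is read from the z-scored, Gaussian-smoothed
($\sigma = 10$ ms) excitatory rate over [3, 7] s:

$$\mathrm{ITPC}(T, f) = \Bigl|\tfrac{1}{T}\sum_{m=1}^{T} F_m(f)/|F_m(f)|\Bigr|,$$

with per-trial reseeding of everything except the stimulus realization.
See the vignette (`vignettes/steady-state-entrainment.Rmd`) for the full
account of model, parameters and numerical choices.

## Worked example

A scaled-down condition (1200 neurons, E/I 4:1, 40 Hz stimulus, 5 trials):

```r
library(assrnet)
cond <- scaled_preset(0.1, n_trials = 5, base_seed = 42)
res <- run_condition(cond, delta_fs = c(1, 2, 3))
print(res)
#> <condition_result> 5/5 trials ok, median 346 spikes/trial
#> <spectral_summary> 5 trials, F_s = 40 Hz, 20001 frequencies (0.25 Hz resolution)
#>  f_s delta_f mean_itpc sd_itpc mean_band_power sd_band_power n_trials
#>   40       1         1       0    0.0005645572             0        5
#>   40       2         1       0    0.0003038016             0        5
#>   40       3         1       0    0.0002157120             0        5
```

Each row is one band half-width $\Delta f_s$ around the stimulus frequency:
`mean_itpc` is the cross-trial phase coherence averaged over
$[F_s - \Delta f_s, F_s + \Delta f_s]$ (1 = perfect phase locking) and
`mean_band_power` the trial-averaged normalized power in the same band. At
this reduced scale the network has no autonomous activity, so responses are
purely stimulus-evoked and locking is perfect; near publication scale
(`scaled_preset(1)`) recurrent activity ignites and competes with the
stimulus, which is the phenomenon of interest. The full experiment grid —
E/I ratios 3:1 through 9:1, the four stimulus frequencies (periods 25, 12,
11, 7 ms), with and without strong (> 9 mV) synapses, 10 trials each — runs
via:

```r
sweep <- run_ei_sweep(ratios = 3:9, periods_ms = c(25, 12, 11, 7),
                      strong_flags = c(FALSE, TRUE),
                      template = scaled_preset(1))
```

(a multi-hour single-core computation at publication scale). A thin CLI
(`exec/assrnet`) exposes `build`, `stimulate`, `simulate`, `analyze` and
`sweep` subcommands over the same functions, with YAML run configs
(`read_condition_config()`).

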