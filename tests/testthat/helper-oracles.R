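## Shared fixtures and independent oracles for the test suite.

## A network with no synapses (n_e excitatory, n_i inhibitory neurons).
empty_table <- function(n_e, n_i = 0L) {
  synapse_table(data.frame(pre_id = integer(0), post_id = integer(0),
                           class_pair = character(0), weight = numeric(0),
                           delay_ms = numeric(0), epsp_mv = numeric(0),
                           p_fail = numeric(0)),
                n_e = n_e, n_i = n_i)
}

## A hand-built stimulus train with prescribed event times.
manual_train <- function(time_ms, neuron_id, spec) {
  o <- order(time_ms)
  structure(data.frame(time_ms = time_ms[o], neuron_id = neuron_id[o]),
            class = c("stimulus_train", "data.frame"),
            spec = spec, n_neurons = max(neuron_id) + 1L)
}

## The EPSP amplitude density as printed: p(x) = exp(-(log x - mu)^2 /
## (2 sigma^2)) / (sqrt(2 pi) sigma x). Written out directly so quadrature
## over it is independent of the sampling path.
epsp_density <- function(x, mu = log(0.2) + 1, sigma = 1) {
  ifelse(x > 0,
         exp(-(log(x) - mu)^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma * x),
         0)
}

## Probability mass of the density on (lo, hi], by quadrature.
epsp_mass <- function(lo, hi, mu = log(0.2) + 1, sigma = 1) {
  stats::integrate(epsp_density, lo, hi, mu = mu, sigma = sigma,
                   rel.tol = 1e-10)$value
}

## Mean resultant length of a set of phase angles (circular statistics).
mrl <- function(theta) Mod(mean(exp(1i * theta)))

## Direct angle-based ITPC of a list of rate series: the oracle that itpc()
## must agree with to machine precision.
itpc_by_angles <- function(trials) {
  n <- length(trials[[1]]$values)
  n_half <- floor(n / 2) + 1L
  Fm <- vapply(trials, function(s) stats::fft(s$values)[seq_len(n_half)],
               complex(n_half))
  Fm <- matrix(Fm, nrow = n_half)
  apply(Fm, 1, function(row) {
    row <- row[Mod(row) > 0]
    if (!length(row)) return(NA_real_)
    mrl(Arg(row))
  })
}

## Linearized closed-form peak of the single-synapse EPSP (valid for small
## conductance): peak = (V_E - V_L) G (e^{-t*/tau_m} - e^{-t*/tau_s}) /
## (1/tau_s - 1/tau_m) with t* = log(tau_m/tau_s) / (1/tau_s - 1/tau_m).
epsp_peak_linear <- function(G, tau_m = 20, tau_s = 2, V_E = 0, V_L = -70) {
  k <- 1 / tau_s - 1 / tau_m
  t_star <- log(tau_m / tau_s) / k
  (V_E - V_L) * G * (exp(-t_star / tau_m) - exp(-t_star / tau_s)) / k
}

## Sinusoidal rate series on the analysis grid.
sinusoid_series <- function(f_hz, phase = 0, window_s = 1, dt_ms = 0.1,
                            amplitude = 1, offset = 0) {
  n <- round(window_s * 1000 / dt_ms)
  t_s <- (seq_len(n) - 1) * dt_ms / 1000
  rate_series(offset + amplitude * sin(2 * pi * f_hz * t_s + phase),
              dt_ms = dt_ms)
}
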