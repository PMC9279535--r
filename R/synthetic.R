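## Synthetic inputs with known statistical structure, so every analysis stage
## is testable without running the simulator.

## von Mises sampler (Best & Fisher 1979 rejection scheme); kappa = 0 gives
## the uniform circle, kappa = Inf perfect concentration at the mean 0.
rvonmises <- function(n, kappa) {
  if (!is.finite(kappa)) return(rep(0, n))
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    z <- cos(pi * runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(runif(1) - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

#' Phase-jittered periodic surrogate trials
#'
#' Trial `m` is a sinusoid at `f_hz` whose phase is drawn from a von Mises
#' distribution of concentration `kappa` (centred at 0), plus white Gaussian
#' noise. The expected ITPC at `f_hz` is the von Mises mean resultant length
#' \eqn{I_1(\kappa) / I_0(\kappa)} (for `noise_sd = 0`), which makes these
#' trials the analytic test harness of [itpc()]: `kappa = Inf` gives perfect
#' locking (ITPC 1), `kappa = 0` uniform phase (ITPC of order
#' \eqn{T^{-1/2}}).
#'
#' @param f_hz Target frequency, Hz (use a grid frequency, i.e. a multiple of
#'   `1 / window_s`).
#' @param kappa von Mises concentration, `>= 0` (may be `Inf`).
#' @param n_trials Number of trials.
#' @param window_s Trial duration, s.
#' @param dt_ms Time grid, ms.
#' @param noise_sd Additive white-noise standard deviation (signal has unit
#'   amplitude).
#' @param seed Optional integer seed.
#' @return List of `n_trials` [rate_series()].
#' @export
#' @examples
#' tr <- make_phase_jittered_trials(40, kappa = Inf, n_trials = 5,
#'                                  window_s = 1, seed = 1)
#' band_mean(itpc(tr), 40, 0)  # 1
make_phase_jittered_trials <- function(f_hz, kappa, n_trials, window_s = 4,
                                       dt_ms = 0.1, noise_sd = 0,
                                       seed = NULL) {
  stopifnot(kappa >= 0, n_trials >= 1, window_s > 0, f_hz > 0)
  n <- round(window_s * 1000 / dt_ms)
  t_s <- (seq_len(n) - 1) * dt_ms / 1000
  with_stream(if (is.null(seed)) NULL else stream_seed(seed, "surrogate"), {
    phases <- rvonmises(n_trials, kappa)
    lapply(seq_len(n_trials), function(m) {
      x <- sin(2 * pi * f_hz * t_s + phases[m])
      if (noise_sd > 0) x <- x + rnorm(n, sd = noise_sd)
      rate_series(x, dt_ms = dt_ms, t0_ms = 0, population = "surrogate")
    })
  })
}

#' Inhomogeneous-Poisson spike trains with a prescribed rate profile
#'
#' Thinning-based generation: homogeneous candidate events at the profile
#' maximum are kept with probability `rate(t) / max(rate)`, independently per
#' neuron. The binned population rate of the output converges to the profile,
#' which exercises the [population_rate()] pipeline end to end.
#'
#' @param rate_profile A [rate_series()] of non-negative per-neuron rates, Hz.
#' @param n_neurons Number of neurons (all treated as excitatory).
#' @param seed Optional integer seed.
#' @return A [spike_record()] with `n_e = n_neurons`, `n_i = 0`.
#' @export
make_inhomogeneous_poisson_spikes <- function(rate_profile, n_neurons,
                                              seed = NULL) {
  stopifnot(inherits(rate_profile, "rate_series"), n_neurons >= 1)
  r <- rate_profile$values
  if (any(r < 0)) stop("make_inhomogeneous_poisson_spikes: negative rates")
  dt <- rate_profile$dt_ms
  duration <- length(r) * dt
  rmax <- max(r)
  ev <- with_stream(if (is.null(seed)) NULL else stream_seed(seed, "poisson"), {
    if (rmax == 0) {
      data.frame(time_ms = numeric(0), neuron_id = integer(0))
    } else {
      n_cand <- rpois(1, n_neurons * rmax * duration / 1000)
      t <- runif(n_cand, 0, duration)
      keep <- runif(n_cand) < r[pmin(floor(t / dt) + 1, length(r))] / rmax
      t <- t[keep]
      id <- sample.int(n_neurons, length(t), replace = TRUE) - 1L
      o <- order(t)
      data.frame(time_ms = t[o], neuron_id = id[o])
    }
  })
  spike_record(ev, n_e = n_neurons, n_i = 0L, duration_ms = duration,
               dt_ms = dt)
}

#' Scaled preset of the publication configuration
#'
#' The publication configuration is 12000 neurons, E:I 4:1, coupling
#' probabilities 0.1/0.5, the standard weights and delays, a 40 Hz stimulus
#' (25 ms period, \eqn{\Lambda} = 1 Hz, 1 ms window, 21 mV), 7 s simulated at
#' 0.1 ms with the `[3, 7]` s analysis window, and 10 trials. `scale` shrinks
#' the neuron count while preserving probabilities and weights (so in-degrees
#' shrink proportionally); quantitative publication-scale claims hold only at
#' `scale = 1`.
#'
#' @param scale Fraction of the publication network size, in `(0, 1]`.
#' @param ei_ratio E:I ratio (scalar `x` for `x:1`).
#' @param period_ms Stimulus period, ms.
#' @param remove_strong Remove strong EE synapses?
#' @param n_trials Trials per condition.
#' @param base_seed Master seed.
#' @return A [condition_spec()].
#' @export
#' @examples
#' scaled_preset(0.1)$network$n_total  # 1200
scaled_preset <- function(scale = 1, ei_ratio = 4, period_ms = 25,
                          remove_strong = FALSE, n_trials = 10,
                          base_seed = 1) {
  if (scale <= 0 || scale > 1) stop("scaled_preset: scale must lie in (0, 1]")
  n_total <- round(12000 * scale)
  spec <- network_spec(n_total = n_total, ei_ratio = ei_ratio,
                       remove_strong = remove_strong)
  if (spec$n_i < 10)
    stop("scaled_preset: scale leaves fewer than 10 inhibitory neurons")
  condition_spec(network = spec, epsp = epsp_spec(),
                 stimulus = stimulus_spec(period_ms = period_ms,
                                          duration_ms = 7000),
                 sim = sim_config(dt_ms = 0.1, duration_ms = 7000,
                                  record_from_ms = 3000),
                 n_trials = n_trials, base_seed = base_seed)
}
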