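#' Membrane and synapse parameters for one neuron class
#'
#' Defaults are the cortical parameter set used throughout the package:
#' leak reversal \eqn{V_L = -70} mV, excitatory reversal \eqn{V_E = 0} mV,
#' inhibitory reversal \eqn{V_I = -80} mV, reset \eqn{V_r = -60} mV,
#' threshold \eqn{V_{thr} = -50} mV, membrane decay constant
#' \eqn{\tau_m = 20} ms (excitatory) or 10 ms (inhibitory), synaptic decay
#' constant \eqn{\tau_s = 2} ms and a 1 ms absolute refractory period.
#'
#' @param class `"excitatory"` or `"inhibitory"`; picks the default `tau_m`.
#' @param tau_m Membrane decay constant, ms. `NULL` = class default.
#' @param V_L,V_E,V_I,V_r,V_thr Leak/excitatory/inhibitory reversal, reset and
#'   threshold potentials, mV.
#' @param tau_s Synaptic conductance decay constant, ms.
#' @param refractory Absolute refractory period, ms.
#' @return An object of class `neuron_params` (a named list).
#' @export
#' @examples
#' neuron_params("inhibitory")$tau_m  # 10 ms
neuron_params <- function(class = c("excitatory", "inhibitory"),
                          tau_m = NULL, V_L = -70, V_E = 0, V_I = -80,
                          V_r = -60, V_thr = -50, tau_s = 2, refractory = 1) {
  class <- match.arg(class)
  if (is.null(tau_m)) tau_m <- if (class == "excitatory") 20 else 10
  p <- list(class = class, tau_m = tau_m, V_L = V_L, V_E = V_E, V_I = V_I,
            V_r = V_r, V_thr = V_thr, tau_s = tau_s, refractory = refractory)
  if (!(p$V_r < p$V_thr)) stop("neuron_params: V_r must be below V_thr")
  if (!(p$V_I <= p$V_L && p$V_L < p$V_thr && p$V_thr < p$V_E))
    stop("neuron_params: require V_I <= V_L < V_thr < V_E")
  if (p$tau_m <= 0 || p$tau_s <= 0 || p$refractory < 0)
    stop("neuron_params: tau_m, tau_s must be positive and refractory >= 0")
  structure(p, class = "neuron_params")
}

#' Truncated log-normal EPSP amplitude distribution
#'
#' The EE synaptic amplitude \eqn{V_{EPSP}} (mV) is log-normally distributed
#' with density \eqn{p(x) = \exp[-(\log x - \mu)^2 / 2\sigma^2] /
#' (\sqrt{2\pi}\,\sigma x)}; the location is parameterized through the mode,
#' \eqn{\mu = \log(\mathrm{mode}) + \sigma^2}, so the density argmax equals
#' `mode_mv`. Draws above `vmax_mv` are rejected and redrawn. Amplitudes above
#' `strong_threshold_mv` define the "strong" synapses of the heavy tail.
#'
#' @param sigma Shape parameter (dimensionless).
#' @param mode_mv Mode of the distribution, mV.
#' @param vmax_mv Rejection ceiling, mV.
#' @param strong_threshold_mv Strong-synapse cutoff, mV.
#' @return An object of class `epsp_spec` with the derived location `mu`.
#' @export
#' @examples
#' s <- epsp_spec()
#' exp(s$mu - s$sigma^2)  # the mode, 0.2 mV
epsp_spec <- function(sigma = 1.0, mode_mv = 0.2, vmax_mv = 20,
                      strong_threshold_mv = 9) {
  if (!is.numeric(sigma) || sigma <= 0) stop("epsp_spec: sigma must be > 0")
  if (!is.numeric(mode_mv) || mode_mv <= 0) stop("epsp_spec: mode_mv must be > 0")
  if (vmax_mv <= mode_mv) stop("epsp_spec: vmax_mv must exceed the mode")
  structure(list(sigma = sigma, mode_mv = mode_mv,
                 mu = log(mode_mv) + sigma^2,
                 vmax_mv = vmax_mv, strong_threshold_mv = strong_threshold_mv),
            class = "epsp_spec")
}

#' Network architecture specification
#'
#' Directed Erdos-Renyi connectivity with class-dependent outgoing coupling
#' probabilities (0.1 for excitatory sources, 0.5 for inhibitory), fixed
#' non-EE synaptic weights, class-dependent uniform delay ranges, and the
#' transmission-failure constant `a_mv` of the failure rule
#' \eqn{P_E = a / (a + V_{EPSP})}.
#'
#' @param n_total Total neuron count (12000 at publication scale).
#' @param ei_ratio Either a scalar `x` meaning an `x:1` excitatory:inhibitory
#'   ratio, or a length-2 vector `c(N_E, N_I)`. Non-integer splits are rounded
#'   to the nearest integers preserving `n_total`.
#' @param p_conn_exc,p_conn_inh Outgoing connection probability per
#'   excitatory / inhibitory source neuron.
#' @param G_EI,G_IE,G_II Fixed synaptic weights (conductance per ms) for
#'   excitatory-to-inhibitory, inhibitory-to-excitatory and
#'   inhibitory-to-inhibitory synapses.
#' @param delay_ee_ms,delay_other_ms Uniform delay ranges, ms, for EE and all
#'   other synapses.
#' @param a_mv Failure constant, mV.
#' @param remove_strong If `TRUE`, [build_network()] deletes EE synapses with
#'   amplitude above the strong-synapse threshold.
#' @return An object of class `network_spec` with resolved `n_e`, `n_i`.
#' @export
#' @examples
#' network_spec(n_total = 1200, ei_ratio = 4)[c("n_e", "n_i")]
network_spec <- function(n_total = 12000, ei_ratio = 4,
                         p_conn_exc = 0.1, p_conn_inh = 0.5,
                         G_EI = 0.018, G_IE = 0.002, G_II = 0.0025,
                         delay_ee_ms = c(1, 3), delay_other_ms = c(0, 2),
                         a_mv = 0.1, remove_strong = FALSE) {
  if (length(ei_ratio) == 2) {
    n_e <- as.integer(ei_ratio[1]); n_i <- as.integer(ei_ratio[2])
    n_total <- n_e + n_i
  } else {
    n_e <- as.integer(round(n_total * ei_ratio / (ei_ratio + 1)))
    n_i <- as.integer(n_total) - n_e
  }
  if (n_e < 1 || n_i < 1) stop("network_spec: need at least one neuron per class")
  if (p_conn_exc < 0 || p_conn_exc > 1 || p_conn_inh < 0 || p_conn_inh > 1)
    stop("network_spec: connection probabilities must lie in [0, 1]")
  for (d in list(delay_ee_ms, delay_other_ms))
    if (length(d) != 2 || d[1] < 0 || d[1] > d[2])
      stop("network_spec: delay ranges must be non-negative with low <= high")
  if (a_mv <= 0) stop("network_spec: a_mv must be positive")
  structure(list(n_total = n_e + n_i, n_e = n_e, n_i = n_i,
                 ei_ratio = n_e / n_i,
                 p_conn_exc = p_conn_exc, p_conn_inh = p_conn_inh,
                 G_EI = G_EI, G_IE = G_IE, G_II = G_II,
                 delay_ee_ms = delay_ee_ms, delay_other_ms = delay_other_ms,
                 a_mv = a_mv, remove_strong = isTRUE(remove_strong)),
            class = "network_spec")
}

#' Simulation configuration
#'
#' @param dt_ms Euler time step, ms.
#' @param duration_ms Total simulated time, ms (7000 at publication scale).
#' @param record_from_ms Start of the analysis window, ms; the interval
#'   `[record_from_ms, duration_ms)` is what the spectral pipeline sees.
#' @param trial_seed Master seed of this trial; the initial-state and
#'   transmission-failure streams are derived from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt_ms = 0.1, duration_ms = 7000,
                       record_from_ms = 3000, trial_seed = 1) {
  if (dt_ms <= 0) stop("sim_config: dt_ms must be positive")
  if (record_from_ms < 0 || record_from_ms >= duration_ms)
    stop("sim_config: record_from_ms must lie in [0, duration_ms)")
  structure(list(dt_ms = dt_ms, duration_ms = duration_ms,
                 record_from_ms = record_from_ms,
                 trial_seed = as.integer(trial_seed)),
            class = "sim_config")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %d neurons (%d E : %d I, ratio %.2f:1)\n",
              x$n_total, x$n_e, x$n_i, x$ei_ratio))
  cat(sprintf("  p_conn E %.3g / I %.3g; G_EI %.4g G_IE %.4g G_II %.4g; a %.3g mV%s\n",
              x$p_conn_exc, x$p_conn_inh, x$G_EI, x$G_IE, x$G_II, x$a_mv,
              if (x$remove_strong) "; strong EE synapses removed" else ""))
  invisible(x)
}
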