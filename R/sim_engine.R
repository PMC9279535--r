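#' Simulate one trial of the network
#'
#' Forward-Euler integration of the conductance-based leaky
#' integrate-and-fire dynamics with threshold/reset, a 1 ms absolute
#' refractory period (the membrane is clamped at `V_r` while conductances
#' keep evolving), per-synapse conduction delays (rounded to the integration
#' grid, delivered at least one step after the spike) and independent
#' Bernoulli transmission failure on EE deliveries. Stimulus events add
#' `amplitude_mv` to the membrane instantaneously; jumps arriving during
#' refractoriness are lost.
#'
#' Initial membrane potentials are drawn uniformly on `[V_L, V_thr)` from the
#' trial's initial-state stream unless `v0` is supplied; initial conductances
#' are zero. Identical inputs and seed give a byte-identical spike record.
#'
#' @param table A [synapse_table()].
#' @param stim A [stimulus_train()][generate_stimulus] (or `NULL` for no
#'   external input).
#' @param cfg A [sim_config()]; `cfg$trial_seed` seeds the initial-state and
#'   transmission-failure streams.
#' @param params_e,params_i [neuron_params()] of the two classes (must share
#'   `tau_s`).
#' @param v0 Optional vector of initial membrane potentials, mV.
#' @param record_v Optional integer vector of 0-based neuron ids whose
#'   membrane trajectory is recorded (one column per id).
#' @return An object of class `spike_record`: a list with `events`
#'   (data.frame `time_ms`, `neuron_id`, time-sorted), `n_e`, `n_i`,
#'   `duration_ms`, `dt_ms` and, if requested, `v_trace`.
#' @export
#' @examples
#' net <- build_network(network_spec(n_total = 100, ei_ratio = 4), seed = 1)
#' st <- generate_stimulus(stimulus_spec(duration_ms = 500), 100, seed = 2)
#' rec <- simulate_trial(net, st, sim_config(duration_ms = 500, record_from_ms = 0))
simulate_trial <- function(table, stim, cfg,
                           params_e = neuron_params("excitatory"),
                           params_i = neuron_params("inhibitory"),
                           v0 = NULL, record_v = NULL) {
  stopifnot(inherits(table, "synapse_table"), inherits(cfg, "sim_config"))
  n_e <- attr(table, "n_e"); n_i <- attr(table, "n_i"); n <- n_e + n_i
  if (params_e$tau_s != params_i$tau_s)
    stop("simulate_trial: the two classes must share tau_s")
  if (!is.null(stim)) {
    stopifnot(inherits(stim, "stimulus_train"))
    if (attr(stim, "n_neurons") > n)
      stop("simulate_trial: stimulus addresses more neurons than the network has")
  }

  dt <- cfg$dt_ms
  n_steps <- round(cfg$duration_ms / dt)

  if (is.null(v0)) {
    v0 <- with_stream(stream_seed(cfg$trial_seed, "initial_state"),
                      runif(n, params_e$V_L, params_e$V_thr))
  }
  stopifnot(length(v0) == n)

  if (is.null(stim) || nrow(stim) == 0) {
    stim_step <- integer(0); stim_neuron <- integer(0); amp <- 0
  } else {
    step <- as.integer(floor(stim$time_ms / dt))
    keep <- step >= 0 & step < n_steps
    o <- order(step[keep])
    stim_step <- step[keep][o]
    stim_neuron <- as.integer(stim$neuron_id[keep][o])
    amp <- attr(stim, "spec")$amplitude_mv
  }

  res <- simulate_trial_cpp(
    pre = as.integer(table$pre_id), post = as.integer(table$post_id),
    weight = as.numeric(table$weight),
    delay_steps = as.integer(round(table$delay_ms / dt)),
    pfail = as.numeric(table$p_fail),
    n_e = n_e, n_i = n_i,
    stim_step = stim_step, stim_neuron = stim_neuron, stim_amp = amp,
    tau_m_e = params_e$tau_m, tau_m_i = params_i$tau_m,
    v_leak = params_e$V_L, v_exc = params_e$V_E, v_inh = params_e$V_I,
    v_reset = params_e$V_r, v_thr = params_e$V_thr,
    tau_s = params_e$tau_s, refractory_ms = params_e$refractory,
    dt = dt, duration_ms = cfg$duration_ms,
    v0 = as.numeric(v0),
    failure_seed = stream_seed(cfg$trial_seed, "failure"),
    record_ids = if (is.null(record_v)) integer(0) else as.integer(record_v))

  out <- list(events = data.frame(time_ms = res$time_ms,
                                  neuron_id = res$neuron_id),
              n_e = n_e, n_i = n_i,
              duration_ms = cfg$duration_ms, dt_ms = dt)
  if (!is.null(record_v)) out$v_trace <- res$v_trace
  structure(out, class = "spike_record")
}

#' Construct a spike record from events
#'
#' @param events Data frame with `time_ms` and `neuron_id` (0-based),
#'   time-sorted.
#' @param n_e,n_i Population sizes.
#' @param duration_ms Covered duration, ms.
#' @param dt_ms Time grid, ms.
#' @return An object of class `spike_record`.
#' @export
spike_record <- function(events, n_e, n_i, duration_ms, dt_ms = 0.1) {
  stopifnot(all(c("time_ms", "neuron_id") %in% names(events)))
  structure(list(events = events, n_e = as.integer(n_e), n_i = as.integer(n_i),
                 duration_ms = duration_ms, dt_ms = dt_ms),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("<spike_record> %d spikes, %d E + %d I neurons, %g ms at dt %g ms\n",
              nrow(x$events), x$n_e, x$n_i, x$duration_ms, x$dt_ms))
  invisible(x)
}
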