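#' Specify one experimental condition
#'
#' A condition is one cell of the experiment grid: a network architecture, an
#' EPSP distribution, a stimulus, a simulation configuration and a trial
#' count. Across the condition's trials the stimulus realization is pinned
#' (one stream derived from `base_seed`) while topology, amplitudes, delays,
#' initial state and transmission failures are reseeded per trial.
#'
#' @param network A [network_spec()].
#' @param epsp An [epsp_spec()].
#' @param stimulus A [stimulus_spec()].
#' @param sim A [sim_config()].
#' @param n_trials Number of trials (10 at publication scale).
#' @param base_seed Master seed of the condition.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(network, epsp = epsp_spec(), stimulus,
                           sim = sim_config(), n_trials = 10, base_seed = 1) {
  stopifnot(inherits(network, "network_spec"), inherits(epsp, "epsp_spec"),
            inherits(stimulus, "stimulus_spec"), inherits(sim, "sim_config"),
            n_trials >= 1)
  structure(list(network = network, epsp = epsp, stimulus = stimulus,
                 sim = sim, n_trials = as.integer(n_trials),
                 base_seed = as.integer(base_seed)),
            class = "condition_spec")
}

## Cross-trial spectral summary from a list of z-scored analysis series.
spectral_summary <- function(zs_list, f_s, delta_fs = c(1, 2, 3)) {
  psd_list <- lapply(zs_list, power_spectrum)
  freq <- psd_list[[1]]$freq_hz
  psd <- vapply(psd_list, function(d) d$power, numeric(length(freq)))
  psd <- matrix(psd, nrow = length(freq))
  it <- itpc(zs_list)
  n_trials <- length(zs_list)

  rows <- list()
  for (df in delta_fs) {
    bp <- vapply(psd_list, band_mean, numeric(1), f_s = f_s, delta_f = df)
    bi <- band_mean(it, f_s, df)
    sd_bi <- NA_real_
    if (n_trials >= 3) {            # leave-one-out spread of the ITPC
      loo <- vapply(seq_len(n_trials), function(m)
        band_mean(itpc(zs_list[-m]), f_s, df), numeric(1))
      sd_bi <- sd(loo)
    }
    rows[[length(rows) + 1]] <- data.frame(
      f_s = f_s, delta_f = df,
      mean_itpc = bi, sd_itpc = sd_bi,
      mean_band_power = mean(bp),
      sd_band_power = if (n_trials >= 2) sd(bp) else NA_real_,
      n_trials = n_trials)
  }
  structure(list(freq_hz = freq,
                 psd = psd,
                 psd_mean = rowMeans(psd),
                 psd_sd = if (n_trials >= 2) apply(psd, 1, sd) else rep(NA_real_, length(freq)),
                 itpc = it,
                 band_means = do.call(rbind, rows),
                 n_trials = n_trials, f_s = f_s),
            class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("<spectral_summary> %d trials, F_s = %.4g Hz, %d frequencies (%g Hz resolution)\n",
              x$n_trials, x$f_s, length(x$freq_hz),
              x$freq_hz[2] - x$freq_hz[1]))
  print(x$band_means, row.names = FALSE)
  invisible(x)
}

#' Run all trials of one condition
#'
#' Generates the condition's stimulus once, then per trial builds a fresh
#' network (reseeded topology, amplitudes, delays), draws fresh initial
#' membrane potentials and transmission failures, simulates, and runs the
#' excitatory-rate analysis pipeline (rate, Gaussian smoothing, z-scoring
#' over `[record_from_ms, duration_ms)`). The per-frequency PSD (per trial
#' and trial-averaged), the cross-trial ITPC and band means around the
#' stimulus frequency are returned.
#'
#' A trial whose analysis window is silent (zero rate variance) is recorded
#' as `"degenerate"` and excluded from the spectral summary; an integration
#' failure aborts the condition with the trial index in the message.
#'
#' @param cond A [condition_spec()].
#' @param delta_fs Band half-widths around `f_s`, Hz.
#' @param sigma_ms Gaussian smoothing width, ms.
#' @param keep_spikes Keep the per-trial [spike_record()]s in the result?
#' @param out_dir Optional directory: per-trial spike files, the stimulus,
#'   the spectral tables and a run manifest are written there.
#' @param verbose Print per-trial progress?
#' @return An object of class `condition_result`: list with `spec`,
#'   `summary` (a `spectral_summary`, or `NULL` if every trial was
#'   degenerate), `trial_status`, `n_spikes`, `stimulus_hash` and optionally
#'   `spike_records`.
#' @export
run_condition <- function(cond, delta_fs = c(1, 2, 3), sigma_ms = 10,
                          keep_spikes = FALSE, out_dir = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(cond, "condition_spec"))
  n <- cond$network$n_total
  stim <- generate_stimulus(cond$stimulus, n,
                            seed = stream_seed(cond$base_seed, "stimulus"))
  window <- c(cond$sim$record_from_ms, cond$sim$duration_ms)

  zs <- vector("list", cond$n_trials)
  status <- character(cond$n_trials)
  n_spikes <- integer(cond$n_trials)
  records <- if (keep_spikes || !is.null(out_dir)) vector("list", cond$n_trials)

  for (m in seq_len(cond$n_trials)) {
    ts <- trial_seed(cond$base_seed, m)
    net <- build_network(cond$network, cond$epsp, seed = ts)
    cfg <- cond$sim
    cfg$trial_seed <- ts
    rec <- tryCatch(simulate_trial(net, stim, cfg),
                    error = function(e)
                      stop(sprintf("condition failed at trial %d: %s", m,
                                   conditionMessage(e)), call. = FALSE))
    n_spikes[m] <- nrow(rec$events)
    if (!is.null(records)) records[[m]] <- rec
    zs[m] <- list(tryCatch(
      analysis_series(rec, window = window, sigma_ms = sigma_ms),
      assrnet_degenerate_error = function(e) NULL))
    status[m] <- if (is.null(zs[[m]])) "degenerate" else "ok"
    if (verbose)
      message(sprintf("trial %d/%d: %d spikes (%s)", m, cond$n_trials,
                      n_spikes[m], status[m]))
  }

  good <- !vapply(zs, is.null, logical(1))
  summary <- if (any(good))
    spectral_summary(zs[good], f_s = cond$stimulus$f_s, delta_fs = delta_fs)

  res <- structure(list(spec = cond, summary = summary,
                        trial_status = status, n_spikes = n_spikes,
                        stimulus_hash = stimulus_hash(stim)),
                   class = "condition_result")
  if (keep_spikes) res$spike_records <- records
  if (!is.null(out_dir)) write_condition_result(res, stim, records, out_dir)
  res
}

## Cheap content hash for stimulus-identity checks across trials/conditions.
stimulus_hash <- function(stim) {
  sprintf("%d-%.6f-%d", nrow(stim),
          if (nrow(stim)) sum(stim$time_ms) else 0,
          if (nrow(stim)) sum(stim$neuron_id) else 0L)
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("<condition_result> %d/%d trials ok, median %d spikes/trial\n",
              sum(x$trial_status == "ok"), length(x$trial_status),
              as.integer(stats::median(x$n_spikes))))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Run the excitatory/inhibitory-ratio sweep
#'
#' Executes the Cartesian product of E/I ratios, stimulus periods and
#' strong-synapse settings, each as a [run_condition()] with a seed derived
#' from the condition's identity (so results are independent of execution
#' order), and collects one summary row per condition and band half-width.
#'
#' @param ratios Numeric vector of E:I ratios `x` (meaning `x:1`); each is
#'   realized as the nearest integer split of the template's `n_total`.
#' @param periods_ms Stimulus periods, ms (see [stimulus_periods()]).
#' @param strong_flags Logical vector: `FALSE` = full log-normal weights,
#'   `TRUE` = strong EE synapses removed.
#' @param template A [condition_spec()] supplying everything else
#'   (`n_total`, probabilities, simulation config, trial count, base seed).
#' @param delta_fs Band half-widths, Hz.
#' @param verbose Print per-condition progress?
#' @return A `data.frame` with one row per (ratio, period, flag, delta_f):
#'   `ei_ratio`, `n_e`, `n_i`, `f_s`, `period_ms`, `strong_synapses`,
#'   `delta_f`, `mean_itpc`, `sd_itpc`, `mean_band_power`, `sd_band_power`,
#'   `n_trials`.
#' @export
run_ei_sweep <- function(ratios, periods_ms, strong_flags = c(FALSE, TRUE),
                         template, delta_fs = c(1, 2, 3), verbose = FALSE) {
  stopifnot(inherits(template, "condition_spec"))
  rows <- list()
  for (ratio in ratios) for (period in periods_ms) for (rm in strong_flags) {
    net <- template$network
    spec <- network_spec(n_total = net$n_total, ei_ratio = ratio,
                         p_conn_exc = net$p_conn_exc,
                         p_conn_inh = net$p_conn_inh,
                         G_EI = net$G_EI, G_IE = net$G_IE, G_II = net$G_II,
                         delay_ee_ms = net$delay_ee_ms,
                         delay_other_ms = net$delay_other_ms,
                         a_mv = net$a_mv, remove_strong = rm)
    st <- template$stimulus
    st <- stimulus_spec(period_ms = period, lambda_hz = st$lambda_hz,
                        window_ms = st$window_ms,
                        amplitude_mv = st$amplitude_mv,
                        duration_ms = st$duration_ms)
    cond_seed <- as.integer((as.numeric(template$base_seed) +
                               1009 * round(1000 * ratio) +
                               31 * round(10 * period) + 17 * rm) %% 2147483629)
    cond <- condition_spec(spec, template$epsp, st, template$sim,
                           n_trials = template$n_trials,
                           base_seed = cond_seed)
    if (verbose)
      message(sprintf("ratio %g:1, period %g ms, %s strong synapses",
                      ratio, period, if (rm) "without" else "with"))
    res <- run_condition(cond, delta_fs = delta_fs)
    bm <- if (is.null(res$summary)) {
      data.frame(f_s = st$f_s, delta_f = delta_fs, mean_itpc = NA_real_,
                 sd_itpc = NA_real_, mean_band_power = NA_real_,
                 sd_band_power = NA_real_, n_trials = 0L)
    } else res$summary$band_means
    bm <- cbind(data.frame(ei_ratio = ratio, n_e = spec$n_e, n_i = spec$n_i,
                           period_ms = period, strong_synapses = !rm),
                bm)
    rows[[length(rows) + 1]] <- bm
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("ei_ratio", "n_e", "n_i", "f_s", "period_ms", "strong_synapses",
          "delta_f", "mean_itpc", "sd_itpc", "mean_band_power",
          "sd_band_power", "n_trials")]
}
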