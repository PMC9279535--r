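## YAML run configuration mirroring condition_spec field for field; every
## model parameter appears with its standard default so a minimal file only
## needs to state what differs.

condition_to_list <- function(cond) {
  net <- cond$network
  list(
    network = list(n_total = net$n_total, n_e = net$n_e, n_i = net$n_i,
                   p_conn_exc = net$p_conn_exc, p_conn_inh = net$p_conn_inh,
                   G_EI = net$G_EI, G_IE = net$G_IE, G_II = net$G_II,
                   delay_ee_ms = net$delay_ee_ms,
                   delay_other_ms = net$delay_other_ms,
                   a_mv = net$a_mv, remove_strong = net$remove_strong),
    epsp = list(sigma = cond$epsp$sigma, mode_mv = cond$epsp$mode_mv,
                vmax_mv = cond$epsp$vmax_mv,
                strong_threshold_mv = cond$epsp$strong_threshold_mv),
    stimulus = list(period_ms = cond$stimulus$period_ms,
                    lambda_hz = cond$stimulus$lambda_hz,
                    window_ms = cond$stimulus$window_ms,
                    amplitude_mv = cond$stimulus$amplitude_mv,
                    duration_ms = cond$stimulus$duration_ms),
    sim = list(dt_ms = cond$sim$dt_ms, duration_ms = cond$sim$duration_ms,
               record_from_ms = cond$sim$record_from_ms),
    n_trials = cond$n_trials,
    base_seed = cond$base_seed)
}

#' Write a condition specification to a YAML config file
#'
#' @param cond A [condition_spec()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_condition_config <- function(cond, path) {
  stopifnot(inherits(cond, "condition_spec"))
  yaml::write_yaml(condition_to_list(cond), path)
  invisible(path)
}

#' Read a condition specification from a YAML config file
#'
#' Unstated fields take the standard defaults of [network_spec()],
#' [epsp_spec()], [stimulus_spec()] and [sim_config()].
#'
#' @param path Config file.
#' @return A [condition_spec()].
#' @export
read_condition_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  take <- function(block, defaults) {
    if (is.null(block)) return(defaults)
    defaults[names(block)[names(block) %in% names(defaults)]] <-
      block[names(block) %in% names(defaults)]
    defaults
  }
  net <- take(cfg$network,
              list(n_total = 12000, ei_ratio = 4, p_conn_exc = 0.1,
                   p_conn_inh = 0.5, G_EI = 0.018, G_IE = 0.002,
                   G_II = 0.0025, delay_ee_ms = c(1, 3),
                   delay_other_ms = c(0, 2), a_mv = 0.1,
                   remove_strong = FALSE))
  if (!is.null(cfg$network$n_e) && !is.null(cfg$network$n_i))
    net$ei_ratio <- c(cfg$network$n_e, cfg$network$n_i)
  ep <- take(cfg$epsp, list(sigma = 1, mode_mv = 0.2, vmax_mv = 20,
                            strong_threshold_mv = 9))
  st <- take(cfg$stimulus, list(period_ms = 25, lambda_hz = 1, window_ms = 1,
                                amplitude_mv = 21, duration_ms = 7000))
  sm <- take(cfg$sim, list(dt_ms = 0.1, duration_ms = 7000,
                           record_from_ms = 3000))
  condition_spec(
    network = network_spec(n_total = net$n_total, ei_ratio = unlist(net$ei_ratio),
                           p_conn_exc = net$p_conn_exc,
                           p_conn_inh = net$p_conn_inh, G_EI = net$G_EI,
                           G_IE = net$G_IE, G_II = net$G_II,
                           delay_ee_ms = unlist(net$delay_ee_ms),
                           delay_other_ms = unlist(net$delay_other_ms),
                           a_mv = net$a_mv, remove_strong = net$remove_strong),
    epsp = epsp_spec(sigma = ep$sigma, mode_mv = ep$mode_mv,
                     vmax_mv = ep$vmax_mv,
                     strong_threshold_mv = ep$strong_threshold_mv),
    stimulus = stimulus_spec(period_ms = st$period_ms,
                             lambda_hz = st$lambda_hz,
                             window_ms = st$window_ms,
                             amplitude_mv = st$amplitude_mv,
                             duration_ms = st$duration_ms),
    sim = sim_config(dt_ms = sm$dt_ms, duration_ms = sm$duration_ms,
                     record_from_ms = sm$record_from_ms),
    n_trials = if (is.null(cfg$n_trials)) 10 else cfg$n_trials,
    base_seed = if (is.null(cfg$base_seed)) 1 else cfg$base_seed)
}
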