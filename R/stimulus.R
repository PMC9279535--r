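#' Canonical stimulus periods
#'
#' The stimulus frequencies studied (40, 83.3, 90.9 and 142.8 Hz) are realized
#' exactly as integer-millisecond periods 25, 12, 11 and 7 ms; all analysis
#' uses the exact frequency `1000 / period_ms`.
#'
#' @return Named numeric vector mapping nominal frequency labels to periods, ms.
#' @export
#' @examples
#' stimulus_periods()
stimulus_periods <- function() {
  c("40" = 25, "83.3" = 12, "90.9" = 11, "142.8" = 7)
}

#' Periodic windowed-Poisson stimulus specification
#'
#' The external input is a Poisson process of rate `lambda_hz` confined to a
#' `window_ms` window at the start of each stimulus period; outside the
#' windows the rate is zero. Each event adds `amplitude_mv` to the membrane
#' potential instantaneously. With the default amplitude (21 mV) a single
#' event at rest exceeds the 20 mV distance from leak to threshold, so every
#' delivered event evokes a spike; the directly evoked firing rate per neuron
#' approximates \eqn{F_s \Lambda / 10^3} Hz.
#'
#' @param period_ms Stimulus period, ms (an integer-ms period; the stimulus
#'   frequency is `1000 / period_ms` Hz). See [stimulus_periods()].
#' @param lambda_hz In-window Poisson rate \eqn{\Lambda}, Hz.
#' @param window_ms Window length, ms.
#' @param amplitude_mv Membrane jump per event, mV.
#' @param duration_ms Stimulated duration, ms (stimulation runs from t = 0
#'   through the full simulation, including any discarded transient).
#' @return An object of class `stimulus_spec` with derived field `f_s` (Hz).
#' @export
stimulus_spec <- function(period_ms = 25, lambda_hz = 1.0, window_ms = 1.0,
                          amplitude_mv = 21, duration_ms = 7000) {
  if (window_ms > period_ms)
    stop("stimulus_spec: window_ms must not exceed the period")
  if (lambda_hz < 0) stop("stimulus_spec: lambda_hz must be non-negative")
  if (duration_ms <= 0) stop("stimulus_spec: duration_ms must be positive")
  structure(list(period_ms = period_ms, f_s = 1000 / period_ms,
                 lambda_hz = lambda_hz, window_ms = window_ms,
                 amplitude_mv = amplitude_mv, duration_ms = duration_ms),
            class = "stimulus_spec")
}

#' Generate per-neuron stimulus event times
#'
#' For each neuron independently, events in each window follow a Poisson
#' process of rate `lambda_hz` (expected `lambda_hz * window_ms / 1000` events
#' per window). The realization is deterministic under `seed`; a condition's
#' trials share one realization (pinned stimulus stream), which is what makes
#' the ITPC informative.
#'
#' @param spec A [stimulus_spec()].
#' @param n_neurons Number of stimulated neurons (ids `0 .. n_neurons-1`).
#' @param seed Optional integer seed.
#' @return A `data.frame` of class `stimulus_train` with columns `time_ms`
#'   (sorted) and `neuron_id`, and attributes `spec`, `n_neurons`.
#' @export
#' @examples
#' st <- generate_stimulus(stimulus_spec(duration_ms = 1000), 100, seed = 1)
#' all(st$time_ms %% 25 < 1)  # every event inside a window
generate_stimulus <- function(spec, n_neurons, seed = NULL) {
  stopifnot(inherits(spec, "stimulus_spec"), n_neurons >= 1)
  n_neurons <- as.integer(n_neurons)
  n_win <- floor(spec$duration_ms / spec$period_ms)
  ## Superposition form of the per-(neuron, window) Poisson draws: the total
  ## count is Poisson with the summed mean and, given the total, events are
  ## iid uniform over neuron x window x within-window offset -- exactly the
  ## same law, vectorized.
  mean_total <- n_neurons * n_win * spec$lambda_hz * spec$window_ms / 1000
  ev <- with_stream(seed, {
    n_ev <- if (mean_total > 0) rpois(1, mean_total) else 0L
    if (n_ev == 0) {
      data.frame(time_ms = numeric(0), neuron_id = integer(0))
    } else {
      neuron <- sample.int(n_neurons, n_ev, replace = TRUE) - 1L
      win <- sample.int(n_win, n_ev, replace = TRUE) - 1L
      t <- win * spec$period_ms + runif(n_ev, 0, spec$window_ms)
      o <- order(t)
      data.frame(time_ms = t[o], neuron_id = neuron[o])
    }
  })
  structure(ev, class = c("stimulus_train", "data.frame"),
            spec = spec, n_neurons = n_neurons)
}

#' @export
print.stimulus_train <- function(x, ...) {
  sp <- attr(x, "spec")
  cat(sprintf(
    "<stimulus_train> %d events, %d neurons, F_s = %.4g Hz (period %g ms), Lambda = %g Hz\n",
    nrow(x), attr(x, "n_neurons"), sp$f_s, sp$period_ms, sp$lambda_hz))
  invisible(x)
}
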