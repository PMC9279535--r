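#' Construct a rate series
#'
#' @param values Rate per time bin, Hz (or z-scored units after
#'   [zscore_window()]).
#' @param dt_ms Bin width, ms.
#' @param t0_ms Time of the first bin, ms.
#' @param population `"E"`, `"I"` or `"surrogate"`.
#' @param smoothed Logical; has [gaussian_smooth()] been applied?
#' @param sigma_ms Smoothing kernel width if smoothed, ms.
#' @param zscored Logical; has [zscore_window()] been applied?
#' @return An object of class `rate_series`.
#' @export
rate_series <- function(values, dt_ms = 0.1, t0_ms = 0, population = "E",
                        smoothed = FALSE, sigma_ms = NA_real_,
                        zscored = FALSE) {
  structure(list(values = as.numeric(values), dt_ms = dt_ms, t0_ms = t0_ms,
                 population = population, smoothed = smoothed,
                 sigma_ms = sigma_ms, zscored = zscored),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("<rate_series> %s, %d bins of %g ms from t = %g ms%s%s\n",
              x$population, length(x$values), x$dt_ms, x$t0_ms,
              if (x$smoothed) sprintf(", smoothed (sigma %g ms)", x$sigma_ms) else "",
              if (x$zscored) ", z-scored" else ""))
  invisible(x)
}

#' Population spiking-rate time series
#'
#' Bins the spikes of one class and scales to Hz:
#' \eqn{r_X(t) = 1000\, S_X(t) / (\Delta t\, N_X)}, where \eqn{S_X(t)} is the
#' class spike count in the bin of width \eqn{\Delta t} ms and \eqn{N_X} the
#' class size.
#'
#' @param spikes A [spike_record()].
#' @param population `"E"` (ids `[0, n_e)`) or `"I"` (ids `[n_e, n_e+n_i)`).
#' @param dt_ms Bin width, ms; defaults to the record's grid.
#' @return A [rate_series()] covering `[0, duration_ms)`.
#' @export
population_rate <- function(spikes, population = c("E", "I"),
                            dt_ms = spikes$dt_ms) {
  stopifnot(inherits(spikes, "spike_record"))
  population <- match.arg(population)
  n_class <- if (population == "E") spikes$n_e else spikes$n_i
  if (n_class < 1) stop("population_rate: empty population ", population)
  sel <- if (population == "E") spikes$events$neuron_id < spikes$n_e
         else spikes$events$neuron_id >= spikes$n_e
  n_bins <- round(spikes$duration_ms / dt_ms)
  ## small epsilon so grid-aligned spike times written to text and re-read
  ## land in their original bin
  idx <- floor(spikes$events$time_ms[sel] / dt_ms + 1e-7) + 1L
  counts <- tabulate(idx[idx >= 1L & idx <= n_bins], nbins = n_bins)
  rate_series(1000 * counts / (dt_ms * n_class), dt_ms = dt_ms, t0_ms = 0,
              population = population)
}

## Same-length convolution with edge mass renormalization so that a constant
## input maps to itself (kernel length must be odd).
conv_same <- function(x, k) {
  m <- length(k)
  h <- (m - 1L) / 2L
  full <- convolve(x, rev(k), type = "open")
  num <- full[(h + 1L):(h + length(x))]
  mass <- convolve(rep(1, length(x)), rev(k), type = "open")[(h + 1L):(h + length(x))]
  num / mass
}

#' Gaussian smoothing of a rate series
#'
#' Convolution with a unit-mass Gaussian kernel truncated at \eqn{\pm 4
#' \sigma}; near the edges the kernel mass falling inside the series is
#' renormalized so constant inputs are preserved exactly. The default
#' \eqn{\sigma = 10} ms matches the membrane time-constant scale.
#'
#' @param series A [rate_series()].
#' @param sigma_ms Kernel standard deviation, ms.
#' @return The smoothed [rate_series()].
#' @export
gaussian_smooth <- function(series, sigma_ms = 10) {
  stopifnot(inherits(series, "rate_series"))
  if (sigma_ms <= 0) stop("gaussian_smooth: sigma_ms must be positive")
  h <- ceiling(4 * sigma_ms / series$dt_ms)
  k <- dnorm((-h:h) * series$dt_ms, sd = sigma_ms)
  k <- k / sum(k)
  out <- series
  out$values <- conv_same(series$values, k)
  out$smoothed <- TRUE
  out$sigma_ms <- sigma_ms
  out
}

#' Restrict a rate series to a window and z-score it
#'
#' Keeps the samples with `t0_ms <= t < t1_ms` (40000 samples for the
#' standard `[3000, 7000)` ms window at 0.1 ms, i.e. 0.25 Hz spectral
#' resolution), subtracts the window mean and divides by the window standard
#' deviation (population form, n denominator), so the mean square of the
#' output is exactly 1.
#'
#' @param series A [rate_series()].
#' @param window Length-2 vector `c(t0_ms, t1_ms)`, ms.
#' @return The z-scored [rate_series()] starting at `window[1]`.
#' @export
zscore_window <- function(series, window = c(3000, 7000)) {
  stopifnot(inherits(series, "rate_series"), length(window) == 2)
  t <- series$t0_ms + (seq_along(series$values) - 1) * series$dt_ms
  sel <- t >= window[1] & t < window[2]
  if (!any(sel)) stop("zscore_window: window outside the series")
  x <- series$values[sel]
  s <- sqrt(mean((x - mean(x))^2))
  if (!is.finite(s) || s == 0)
    stop(errorCondition(
      "zscore_window: zero variance in the analysis window (silent population?)",
      class = c("assrnet_degenerate_error", "error", "condition")))
  out <- series
  out$values <- (x - mean(x)) / s
  out$t0_ms <- window[1]
  out$zscored <- TRUE
  out
}

#' One-sided periodogram of a (z-scored) rate series
#'
#' Plain rectangular-window periodogram of the full segment, normalized so
#' that the one-sided powers sum to the mean square of the input (Parseval;
#' exactly 1 for a [zscore_window()] output). The frequency grid is
#' `k / (N dt)`, 0.25 Hz for the standard 4 s window.
#'
#' @param series A [rate_series()] (finite values).
#' @return A `data.frame` with columns `freq_hz` and `power`.
#' @export
power_spectrum <- function(series) {
  stopifnot(inherits(series, "rate_series"))
  x <- series$values
  if (any(!is.finite(x))) stop("power_spectrum: non-finite values")
  n <- length(x)
  X <- fft(x)
  n_half <- floor(n / 2) + 1L
  p <- Mod(X[seq_len(n_half)])^2 / n^2
  dbl <- seq_len(n_half) > 1 & (seq_len(n_half) - 1) < n / 2
  p[dbl] <- 2 * p[dbl]
  fs_hz <- 1000 / series$dt_ms
  data.frame(freq_hz = (seq_len(n_half) - 1) * fs_hz / n, power = p)
}

#' Inter-trial phase coherence
#'
#' For each frequency on the common grid, the modulus of the across-trial
#' mean of unit-normalized Fourier coefficients:
#' \deqn{\mathrm{ITPC}(T, f) = \left| \frac{1}{T} \sum_{m=1}^{T}
#'   \frac{F_m(f)}{|F_m(f)|} \right|,}
#' equivalently the mean resultant length of the per-trial phase angles.
#' A trial whose coefficient is exactly zero at some frequency carries no
#' phase there and is excluded at that frequency (with a warning); if all
#' trials are excluded the ITPC is `NA` at that frequency.
#'
#' @param trials List of [rate_series()] on the same grid (same length and
#'   `dt_ms`).
#' @return A `data.frame` with columns `freq_hz` and `itpc` (in `[0, 1]`),
#'   with attribute `n_trials`.
#' @export
itpc <- function(trials) {
  stopifnot(is.list(trials), length(trials) >= 1)
  n <- length(trials[[1]]$values)
  dt <- trials[[1]]$dt_ms
  for (s in trials)
    if (!inherits(s, "rate_series") || length(s$values) != n || s$dt_ms != dt)
      stop("itpc: all trials must be rate_series on the same grid")
  n_half <- floor(n / 2) + 1L
  Fm <- vapply(trials, function(s) fft(s$values)[seq_len(n_half)],
               complex(n_half))
  Fm <- matrix(Fm, nrow = n_half)
  mod <- Mod(Fm)
  ok <- mod > 0
  if (any(!ok))
    warning(sprintf("itpc: %d zero Fourier coefficients excluded", sum(!ok)))
  unit <- Fm
  unit[ok] <- Fm[ok] / mod[ok]
  unit[!ok] <- 0
  n_eff <- rowSums(ok)
  val <- ifelse(n_eff > 0, Mod(rowSums(unit)) / n_eff, NA_real_)
  fs_hz <- 1000 / dt
  structure(data.frame(freq_hz = (seq_len(n_half) - 1) * fs_hz / n,
                       itpc = val),
            n_trials = length(trials))
}

#' Mean of a spectral quantity over a band around the stimulus frequency
#'
#' Arithmetic mean of the second column of `x` over the grid frequencies in
#' the closed interval `[f_s - delta_f, f_s + delta_f]`.
#'
#' @param x A `data.frame` whose first column is `freq_hz` and second the
#'   metric ([power_spectrum()] or [itpc()] output).
#' @param f_s Band center, Hz (use the exact frequency, e.g. `1000/12`).
#' @param delta_f Half-width, Hz.
#' @return Scalar band mean (`NA` frequencies are dropped).
#' @export
band_mean <- function(x, f_s, delta_f) {
  stopifnot(is.data.frame(x), ncol(x) >= 2, delta_f >= 0)
  sel <- x[[1]] >= f_s - delta_f & x[[1]] <= f_s + delta_f
  if (!any(sel)) stop("band_mean: no grid frequencies inside the band")
  mean(x[[2]][sel], na.rm = TRUE)
}

#' Rate -> smoothed -> z-scored analysis series for one trial
#'
#' Convenience wrapper running the standard single-trial pipeline:
#' [population_rate()] of the excitatory population, [gaussian_smooth()],
#' [zscore_window()].
#'
#' @param spikes A [spike_record()].
#' @param window Analysis window, ms.
#' @param sigma_ms Smoothing width, ms.
#' @param population Class to analyze.
#' @return A z-scored [rate_series()].
#' @export
analysis_series <- function(spikes, window = c(3000, 7000), sigma_ms = 10,
                            population = "E") {
  zscore_window(gaussian_smooth(population_rate(spikes, population),
                                sigma_ms = sigma_ms),
                window = window)
}
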