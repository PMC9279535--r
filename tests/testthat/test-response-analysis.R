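test_that("population rate implements the binned-count formula and conserves spikes", {
  ev <- data.frame(time_ms = c(0.55, 0.58, 0.59, 3.2, 7.0),
                   neuron_id = c(0L, 1L, 2L, 0L, 1200L))
  rec <- spike_record(ev, n_e = 1000, n_i = 300, duration_ms = 10, dt_ms = 0.1)
  rE <- population_rate(rec, "E")
  ## 3 excitatory spikes in the bin [0.5, 0.6): 1000 * 3 / (0.1 * 1000) = 30 Hz
  expect_equal(rE$values[6], 30)
  expect_equal(sum(rE$values > 0), 2)  # bins [0.5, 0.6) and [3.2, 3.3)
  rI <- population_rate(rec, "I")
  expect_equal(sum(rI$values), 1000 * 1 / (0.1 * 300))

  ## conservation: integral of rate * N / 1000 equals the spike count
  expect_equal(sum(rE$values) * 0.1 * 1000 / 1000, 4)
  expect_equal(sum(rI$values) * 0.1 * 300 / 1000, 1)

  ## empty population errors, no spikes give zeros
  rec0 <- spike_record(ev[0, ], n_e = 10, n_i = 0, duration_ms = 10)
  expect_error(population_rate(rec0, "I"), "empty")
  expect_true(all(population_rate(rec0, "E")$values == 0))
})

test_that("Gaussian smoothing preserves constants, means, and maps impulses to the kernel", {
  const <- rate_series(rep(7, 5000))
  sm <- gaussian_smooth(const, 10)
  expect_equal(sm$values, rep(7, 5000), tolerance = 1e-12)

  set.seed(3)
  x <- rate_series(rpois(20000, 5) * 2)
  sx <- gaussian_smooth(x, 10)
  expect_equal(mean(sx$values[500:19500]), mean(x$values[500:19500]),
               tolerance = 1e-3)

  imp <- rate_series(c(rep(0, 2000), 1, rep(0, 2000)))
  si <- gaussian_smooth(imp, 10)
  expect_equal(which.max(si$values), 2001)
  k <- dnorm((-400:400) * 0.1, sd = 10)
  expect_equal(si$values[1601:2401], k / sum(k), tolerance = 1e-10)
})

test_that("window z-scoring normalizes, is affine-invariant, and rejects silence", {
  set.seed(4)
  s <- rate_series(runif(70000, 0, 50), t0_ms = 0)
  z <- zscore_window(s, c(3000, 7000))
  expect_length(z$values, 40000)
  expect_equal(mean(z$values), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z$values^2)), 1, tolerance = 1e-12)
  expect_equal(z$t0_ms, 3000)

  s2 <- s; s2$values <- 3.7 * s$values + 11
  z2 <- zscore_window(s2, c(3000, 7000))
  expect_equal(z2$values, z$values, tolerance = 1e-9)

  expect_error(zscore_window(rate_series(rep(2, 1000)), c(0, 100)),
               class = "assrnet_degenerate_error")
  expect_error(zscore_window(s, c(8000, 9000)), "window")
})

test_that("the periodogram localizes sinusoids and satisfies Parseval", {
  s <- zscore_window(sinusoid_series(40, window_s = 4, offset = 5),
                     c(0, 4000))
  ps <- power_spectrum(s)
  expect_equal(ps$freq_hz[2] - ps$freq_hz[1], 0.25)
  expect_equal(ps$freq_hz[which.max(ps$power)], 40)
  expect_equal(sum(ps$power), 1, tolerance = 1e-6)

  ## white noise is flat: no systematic log-power trend across frequency
  set.seed(5)
  acc <- 0
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    z <- zscore_window(rate_series(rnorm(2048), dt_ms = 1), c(0, 2048))
    acc <- acc + power_spectrum(z)$power
  }
  pm <- acc / n_rep
  f <- power_spectrum(zscore_window(rate_series(rnorm(2048), dt_ms = 1),
                                    c(0, 2048)))$freq_hz
  sel <- f > 0 & f < 500
  fit <- stats::lm(log(pm[sel]) ~ f[sel])
  drift <- abs(coef(fit)[2]) * 500   # total log-power drift over the band
  expect_lt(drift, 0.05)
})

test_that("ITPC is 1 for identical trials, cancels opposed phases, ignores amplitude", {
  base <- sinusoid_series(40, phase = 0.7, window_s = 1, offset = 2)
  same <- replicate(5, base, simplify = FALSE)
  it <- itpc(same)
  expect_lt(max(abs(it$itpc[!is.na(it$itpc)] - 1)), 1e-12)
  expect_equal(band_mean(it, 40, 0), 1)

  opposed <- lapply(c(0, pi / 2, pi, 3 * pi / 2), function(ph)
    sinusoid_series(40, phase = ph, window_s = 1))
  expect_lt(band_mean(itpc(opposed), 40, 0), 1e-10)

  set.seed(6)
  trials <- lapply(1:6, function(i) rate_series(rnorm(1000), dt_ms = 1))
  scaled <- lapply(seq_along(trials), function(i) {
    s <- trials[[i]]; s$values <- s$values * i * 2.5; s
  })
  expect_equal(itpc(scaled)$itpc, itpc(trials)$itpc, tolerance = 1e-12)

  ## degenerate single-trial case: unit modulus everywhere retained
  one <- itpc(trials[1])
  expect_lt(max(abs(one$itpc[!is.na(one$itpc)] - 1)), 1e-12)
})

test_that("band means average the closed frequency interval", {
  df <- data.frame(freq_hz = seq(0, 100, by = 0.25), value = 3)
  expect_equal(band_mean(df, 40, 2), 3)
  df$value <- ifelse(df$freq_hz == 40, 10, 0)
  expect_equal(band_mean(df, 40, 0), 10)
  ## widening the band around an isolated peak dilutes the mean
  m <- vapply(c(1, 2, 3), function(d) band_mean(df, 40, d), numeric(1))
  expect_true(all(diff(m) < 0))
  ## closed interval: both endpoints included
  expect_equal(band_mean(df, 39, 1), 10 / 9)
  expect_error(band_mean(df, 200, 1), "band")
})
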