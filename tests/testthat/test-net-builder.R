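test_that("EPSP amplitude sampling follows the truncated log-normal law", {
  spec <- epsp_spec()
  expect_identical(sample_epsp_amplitudes(0, spec, seed = 1), numeric(0))

  x <- sample_epsp_amplitudes(1e5, spec, seed = 42)
  expect_length(x, 1e5)
  expect_true(all(x > 0 & x <= spec$vmax_mv))

  ## distribution check against the truncated CDF (closed form, independent
  ## of the rejection sampler's mechanics)
  trunc_cdf <- function(q) {
    stats::plnorm(pmin(q, spec$vmax_mv), spec$mu, spec$sigma) /
      stats::plnorm(spec$vmax_mv, spec$mu, spec$sigma)
  }
  ks <- suppressWarnings(stats::ks.test(x, trunc_cdf))
  expect_gt(ks$p.value, 0.01)

  ## reproducibility of the stream
  expect_identical(sample_epsp_amplitudes(100, spec, seed = 7),
                   sample_epsp_amplitudes(100, spec, seed = 7))
  expect_false(identical(sample_epsp_amplitudes(100, spec, seed = 7),
                         sample_epsp_amplitudes(100, spec, seed = 8)))

  expect_error(epsp_spec(sigma = 0), "sigma")
  expect_error(epsp_spec(mode_mv = -1), "mode")
})

test_that("conductance rule is V_EPSP/100 and rejects bad input", {
  expect_equal(epsp_to_conductance(1.0), 0.01)
  expect_equal(epsp_to_conductance(0.2), 0.002)
  expect_equal(epsp_to_conductance(20), 0.2)
  expect_error(epsp_to_conductance(0), "positive")
  expect_error(epsp_to_conductance(-3), "positive")
})

test_that("single-synapse calibration is zero at zero and monotone sub-linear", {
  expect_equal(calibrate_single_epsp(0), 0)
  w <- c(0.001, 0.002, 0.005, 0.01, 0.02, 0.05, 0.1)
  peaks <- vapply(w, calibrate_single_epsp, numeric(1))
  expect_true(all(diff(peaks) > 0))
  ## sub-linear near threshold: the gain per unit conductance shrinks
  gain <- peaks / w
  expect_true(all(diff(gain) < 0))
  ## the small-signal peak matches the linearized closed form
  expect_equal(calibrate_single_epsp(1e-4), epsp_peak_linear(1e-4),
               tolerance = 1e-3)
})

test_that("built networks satisfy the structural invariants", {
  set.seed(1)
  cases <- list(
    list(n = 200, ratio = 4, pe = 0.1, pi = 0.5),
    list(n = 150, ratio = 2, pe = 0.3, pi = 0.2),
    list(n = 300, ratio = 9, pe = 0.05, pi = 0.6),
    list(n = 120, ratio = c(60, 60), pe = 0.2, pi = 0.4))
  for (cs in cases) {
    spec <- network_spec(n_total = cs$n, ei_ratio = cs$ratio,
                         p_conn_exc = cs$pe, p_conn_inh = cs$pi)
    net <- build_network(spec, seed = 99)
    n_e <- attr(net, "n_e"); n_i <- attr(net, "n_i")

    expect_true(all(net$pre_id != net$post_id))
    expect_false(any(duplicated(paste(net$pre_id, net$post_id))))
    expect_true(all(net$pre_id >= 0 & net$pre_id < n_e + n_i))
    expect_true(all(net$post_id >= 0 & net$post_id < n_e + n_i))

    ee <- net$class_pair == "EE"
    expect_true(all(net$delay_ms[ee] >= 1 & net$delay_ms[ee] <= 3))
    expect_true(all(net$delay_ms[!ee] >= 0 & net$delay_ms[!ee] <= 2))

    expect_true(all(!is.na(net$epsp_mv[ee])))
    expect_true(all(is.na(net$epsp_mv[!ee])))
    expect_equal(net$weight[ee], net$epsp_mv[ee] / 100)
    expect_equal(net$weight[net$class_pair == "EI"],
                 rep(spec$G_EI, sum(net$class_pair == "EI")))
    expect_equal(net$weight[net$class_pair == "IE"],
                 rep(spec$G_IE, sum(net$class_pair == "IE")))
    expect_equal(net$weight[net$class_pair == "II"],
                 rep(spec$G_II, sum(net$class_pair == "II")))

    ## failure probability identity P_E (a + V) == a, machine precision
    expect_equal(net$p_fail[ee] * (spec$a_mv + net$epsp_mv[ee]),
                 rep(spec$a_mv, sum(ee)))
    expect_true(all(net$p_fail[!ee] == 0))
  }

  ## zero probabilities give an empty table
  net0 <- build_network(network_spec(n_total = 100, ei_ratio = 4,
                                     p_conn_exc = 0, p_conn_inh = 0),
                        seed = 1)
  expect_equal(nrow(net0), 0)
})

test_that("two builds from one stream are identical, different streams differ", {
  spec <- network_spec(n_total = 300, ei_ratio = 4)
  a <- build_network(spec, seed = 5)
  b <- build_network(spec, seed = 5)
  cc <- build_network(spec, seed = 6)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a), as.data.frame(cc)))
})

test_that("strong-synapse ablation deletes exactly the heavy tail, idempotently", {
  spec <- network_spec(n_total = 2000, ei_ratio = 4)
  net <- build_network(spec, seed = 3)
  thr <- 9
  strong <- net$class_pair == "EE" & !is.na(net$epsp_mv) & net$epsp_mv > thr

  cut <- remove_strong_synapses(net, thr)
  expect_equal(nrow(cut), nrow(net) - sum(strong))
  expect_true(all(cut$epsp_mv[cut$class_pair == "EE"] <= thr))
  expect_identical(as.data.frame(remove_strong_synapses(cut, thr)),
                   as.data.frame(cut))
  ## non-EE rows untouched
  expect_equal(sum(cut$class_pair != "EE"), sum(net$class_pair != "EE"))

  ## a table with nothing above threshold is returned unchanged
  weak <- remove_strong_synapses(net, 25)
  expect_identical(as.data.frame(weak), as.data.frame(net))

  ## build_network(remove_strong = TRUE) equals post-hoc ablation of the
  ## same streams
  spec_rm <- network_spec(n_total = 2000, ei_ratio = 4, remove_strong = TRUE)
  expect_identical(as.data.frame(build_network(spec_rm, seed = 3)),
                   as.data.frame(cut))

  ## deleted count matches the quadrature tail mass of the printed density:
  ## expected EE synapses n_e * (n_e - 1) * p, of which tail_frac are strong
  n_e <- attr(net, "n_e")
  tail_frac <- epsp_mass(thr, 20) / epsp_mass(0, 20)
  expected_strong <- n_e * (n_e - 1) * spec$p_conn_exc * tail_frac
  expect_lt(abs(sum(strong) - expected_strong), 3 * sqrt(expected_strong))
})
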