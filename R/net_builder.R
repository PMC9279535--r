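#' Sample EPSP amplitudes from the truncated log-normal distribution
#'
#' Draws from the log-normal density with location `spec$mu` and shape
#' `spec$sigma`; draws exceeding `spec$vmax_mv` are rejected and redrawn
#' (truncation by redrawing, not clipping).
#'
#' @param n Number of amplitudes.
#' @param spec An [epsp_spec()].
#' @param seed Optional integer seed; when given, the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return Numeric vector of `n` amplitudes in `(0, vmax_mv]`, mV.
#' @export
#' @examples
#' x <- sample_epsp_amplitudes(1000, epsp_spec(), seed = 1)
#' max(x) <= 20
sample_epsp_amplitudes <- function(n, spec = epsp_spec(), seed = NULL) {
  stopifnot(inherits(spec, "epsp_spec"), is.numeric(n), n >= 0)
  n <- as.integer(n)
  if (n == 0) return(numeric(0))
  with_stream(seed, {
    x <- rlnorm(n, meanlog = spec$mu, sdlog = spec$sigma)
    repeat {
      bad <- which(x > spec$vmax_mv)
      if (!length(bad)) break
      x[bad] <- rlnorm(length(bad), meanlog = spec$mu, sdlog = spec$sigma)
    }
    x
  })
}

#' Convert an EPSP amplitude to a synaptic conductance weight
#'
#' Applies the calibration rule \eqn{G_{EE} = V_{EPSP} / 100}: the conductance
#' increment (per ms) whose single-synapse response peaks at approximately
#' `epsp_mv` millivolts above rest. [calibrate_single_epsp()] is the
#' independent check of this rule.
#'
#' @param epsp_mv Positive EPSP amplitude(s), mV.
#' @return Conductance weight(s), per ms.
#' @export
epsp_to_conductance <- function(epsp_mv) {
  if (!is.numeric(epsp_mv) || any(!is.finite(epsp_mv)) || any(epsp_mv <= 0))
    stop("epsp_to_conductance: amplitudes must be positive and finite")
  epsp_mv / 100
}

#' Peak depolarization evoked by a single excitatory synapse
#'
#' Integrates the two-ODE single-synapse system
#' \deqn{dv/dt = -(v - V_L)/\tau_m - g_E (v - V_E), \quad
#'       dg_E/dt = -g_E/\tau_s,}
#' from \eqn{v(0) = V_L}, \eqn{g_E(0) = } `weight` (the delta input integrated
#' exactly) and returns the peak of \eqn{v(t) - V_L}. Used as the independent
#' oracle for the \eqn{G = V_{EPSP}/100} rule of [epsp_to_conductance()].
#'
#' @param weight Conductance jump, per ms (non-negative).
#' @param params [neuron_params()] of the postsynaptic neuron.
#' @param dt_ms Integration step of the RK4 solver, ms (at most 0.1).
#' @param t_max_ms Integration horizon, ms; the response peaks within a few
#'   membrane time constants.
#' @return Peak depolarization above rest, mV.
#' @export
#' @examples
#' calibrate_single_epsp(0.002)  # approx 0.2 mV
calibrate_single_epsp <- function(weight, params = neuron_params("excitatory"),
                                  dt_ms = 0.01, t_max_ms = 100) {
  stopifnot(is.numeric(weight), length(weight) == 1, weight >= 0,
            inherits(params, "neuron_params"))
  if (dt_ms > 0.1) stop("calibrate_single_epsp: dt_ms must be <= 0.1 ms")
  if (weight == 0) return(0)
  rhs <- function(t, y, p) {
    list(c(-(y[1] - p$V_L) / p$tau_m - y[2] * (y[1] - p$V_E),
           -y[2] / p$tau_s))
  }
  out <- deSolve::ode(y = c(v = params$V_L, g = weight),
                      times = seq(0, t_max_ms, by = dt_ms),
                      func = rhs, parms = params, method = "rk4")
  max(out[, "v"]) - params$V_L
}

#' Build a random network as a synapse table
#'
#' Every ordered pair `(pre, post)` with `pre != post` is connected
#' independently with the outgoing probability of the presynaptic class
#' (`p_conn_exc` / `p_conn_inh`). EE synapses get log-normal EPSP amplitudes,
#' weight `epsp_mv / 100` and failure probability `a / (a + epsp_mv)`; EI, IE
#' and II synapses get the fixed weights and never fail. Delays are uniform in
#' the class range (`[1,3]` ms EE, `[0,2]` ms otherwise). Neuron ids are
#' 0-based with excitatory ids `[0, n_e)` and inhibitory ids `[n_e, n_e+n_i)`.
#'
#' @param spec A [network_spec()].
#' @param epsp An [epsp_spec()].
#' @param seed Master seed; topology, amplitudes and delays consume separate
#'   streams derived from it (see [stream_seed()]).
#' @return A `data.frame` of class `synapse_table` with columns `pre_id`,
#'   `post_id`, `class_pair`, `weight`, `delay_ms`, `epsp_mv` (`NA` off EE)
#'   and `p_fail`, plus attributes `n_e`, `n_i`.
#' @export
#' @examples
#' net <- build_network(network_spec(n_total = 200, ei_ratio = 4), seed = 1)
#' table(net$class_pair)
build_network <- function(spec, epsp = epsp_spec(), seed = 1) {
  stopifnot(inherits(spec, "network_spec"), inherits(epsp, "epsp_spec"))
  n_e <- spec$n_e; n_i <- spec$n_i; n <- n_e + n_i

  p_src <- c(rep(spec$p_conn_exc, n_e), rep(spec$p_conn_inh, n_i))
  topo <- with_stream(stream_seed(seed, "topology"), {
    counts <- rbinom(n, n - 1L, p_src)
    tgt <- vector("list", n)
    for (i in seq_len(n)) {
      k <- counts[i]
      if (k == 0) { tgt[[i]] <- integer(0); next }
      t0 <- sample.int(n - 1L, k) - 1L        # 0-based over candidates
      sel <- t0 >= (i - 1L)                   # skip self (source is i-1)
      t0[sel] <- t0[sel] + 1L
      tgt[[i]] <- t0
    }
    list(counts = counts, tgt = tgt)
  })

  pre <- rep.int(0:(n - 1L), topo$counts)
  post <- unlist(topo$tgt, use.names = FALSE)
  if (is.null(post)) post <- integer(0)
  code <- 2L * (pre < n_e) + (post < n_e)      # 3=EE, 2=EI, 1=IE, 0=II
  class_pair <- c("II", "IE", "EI", "EE")[code + 1L]
  is_ee <- code == 3L

  delay_ms <- with_stream(stream_seed(seed, "delays"), {
    d <- runif(length(pre), spec$delay_other_ms[1], spec$delay_other_ms[2])
    d[is_ee] <- runif(sum(is_ee), spec$delay_ee_ms[1], spec$delay_ee_ms[2])
    d
  })

  epsp_mv <- rep(NA_real_, length(pre))
  epsp_mv[is_ee] <- sample_epsp_amplitudes(sum(is_ee), epsp,
                                           seed = stream_seed(seed, "epsp"))

  weight <- c(spec$G_II, spec$G_IE, spec$G_EI, 0)[code + 1L]
  weight[is_ee] <- epsp_mv[is_ee] / 100

  p_fail <- numeric(length(pre))
  p_fail[is_ee] <- spec$a_mv / (spec$a_mv + epsp_mv[is_ee])

  tab <- data.frame(pre_id = pre, post_id = post, class_pair = class_pair,
                    weight = weight, delay_ms = delay_ms,
                    epsp_mv = epsp_mv, p_fail = p_fail,
                    stringsAsFactors = FALSE)
  tab <- synapse_table(tab, n_e = n_e, n_i = n_i)
  if (spec$remove_strong)
    tab <- remove_strong_synapses(tab, epsp$strong_threshold_mv)
  tab
}

#' Construct a synapse table from a data frame
#'
#' Low-level constructor used by [build_network()] and by tests that need
#' hand-built micro-circuits.
#'
#' @param df Data frame with columns `pre_id`, `post_id`, `class_pair`,
#'   `weight`, `delay_ms`, `epsp_mv`, `p_fail`.
#' @param n_e,n_i Population sizes.
#' @return The data frame with class `synapse_table` and attributes set.
#' @export
synapse_table <- function(df, n_e, n_i) {
  need <- c("pre_id", "post_id", "class_pair", "weight", "delay_ms",
            "epsp_mv", "p_fail")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("synapse_table: missing columns ", paste(miss, collapse = ", "))
  structure(df, class = c("synapse_table", "data.frame"),
            n_e = as.integer(n_e), n_i = as.integer(n_i))
}

#' Delete strong excitatory-to-excitatory synapses
#'
#' Removes every EE synapse with amplitude strictly above `threshold_mv`
#' (deletion, not resampling: the ablation removes the heavy tail of the
#' weight distribution). All other synapses are untouched; the operation is
#' idempotent.
#'
#' @param table A [synapse_table()].
#' @param threshold_mv Strong-synapse cutoff, mV.
#' @return The filtered synapse table.
#' @export
remove_strong_synapses <- function(table, threshold_mv = 9) {
  stopifnot(inherits(table, "synapse_table"))
  drop <- table$class_pair == "EE" & !is.na(table$epsp_mv) &
    table$epsp_mv > threshold_mv
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  synapse_table(out, attr(table, "n_e"), attr(table, "n_i"))
}

#' @export
print.synapse_table <- function(x, ...) {
  cat(sprintf("<synapse_table> %d synapses, %d E + %d I neurons\n",
              nrow(x), attr(x, "n_e"), attr(x, "n_i")))
  print(table(x$class_pair))
  invisible(x)
}
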