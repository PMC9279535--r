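## Named RNG streams.  The ITPC protocol requires the stimulus realization to
## be pinned across the trials of a condition while topology, EPSP amplitudes,
## delays, initial state and transmission failures are reseeded per trial;
## deriving each stream's seed deterministically from one master seed keeps
## every run reproducible from a single integer.

.stream_offsets <- c(
  topology = 1L, epsp = 2L, delays = 3L, initial_state = 4L,
  failure = 5L, stimulus = 6L, surrogate = 7L, poisson = 8L
)

#' Derive the seed of a named RNG stream
#'
#' Maps a master seed and a stream name to a deterministic 32-bit seed so that
#' independent parts of a simulation (topology, EPSP amplitudes, delays,
#' initial membrane potentials, transmission failures, stimulus) consume
#' separate random streams.
#'
#' @param seed Master seed (non-negative integer-valued scalar).
#' @param stream One of `"topology"`, `"epsp"`, `"delays"`, `"initial_state"`,
#'   `"failure"`, `"stimulus"`, `"surrogate"`, `"poisson"`.
#' @return An integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' stream_seed(1, "stimulus")
stream_seed <- function(seed, stream) {
  stream <- match.arg(stream, names(.stream_offsets))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 48271 + 7919 * .stream_offsets[[stream]]) %% 2147483629)
}

#' Derive the master seed of one trial from a condition's base seed
#'
#' @param base_seed Condition-level master seed.
#' @param trial Trial index (1-based).
#' @return An integer seed in `[0, 2^31)`.
#' @export
trial_seed <- function(base_seed, trial) {
  stopifnot(is.numeric(base_seed), length(base_seed) == 1,
            is.numeric(trial), length(trial) == 1, trial >= 1)
  as.integer((as.numeric(base_seed) + 1299721 * as.numeric(trial)) %% 2147483629)
}

## Run `expr` under `seed` if non-NULL, restoring the caller's RNG state;
## with seed = NULL the current global RNG is consumed (advanced).
with_stream <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}
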