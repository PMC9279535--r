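## Plain-text serialization: tab-delimited tables with a small '#'-prefixed
## header manifest, so artifacts survive any environment and diff cleanly.

write_header <- function(path, fields) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(fields))
    writeLines(sprintf("# %s: %s", nm, format(fields[[nm]], digits = 15)), con)
}

read_header <- function(path) {
  lines <- readLines(path, n = 50)
  lines <- lines[startsWith(lines, "# ")]
  kv <- regmatches(lines, regexec("^# ([^:]+): (.*)$", lines))
  out <- lapply(kv, `[`, 3)
  names(out) <- vapply(kv, `[`, character(1), 2)
  out
}

append_table <- function(df, path) {
  suppressWarnings(write.table(df, path, append = TRUE, sep = "\t",
                               quote = FALSE, row.names = FALSE))
}

#' Write / read a synapse table
#'
#' Tab-delimited columns `pre_id`, `post_id`, `class_pair`, `weight`,
#' `delay_ms`, `epsp_mv`, `p_fail`; population sizes in a `#`-prefixed
#' header.
#'
#' @param table A [synapse_table()].
#' @param path File path.
#' @return `read_synapse_table()` returns the [synapse_table()];
#'   `write_synapse_table()` returns `path` invisibly.
#' @export
write_synapse_table <- function(table, path) {
  stopifnot(inherits(table, "synapse_table"))
  write_header(path, list(n_e = attr(table, "n_e"), n_i = attr(table, "n_i")))
  append_table(as.data.frame(table), path)
  invisible(path)
}

#' @rdname write_synapse_table
#' @export
read_synapse_table <- function(path) {
  h <- read_header(path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  synapse_table(df, n_e = as.integer(h$n_e), n_i = as.integer(h$n_i))
}

#' Write / read a spike record
#'
#' Two tab-delimited columns (`time_ms`, `neuron_id`), time-sorted, with
#' population sizes, duration and grid in the header.
#'
#' @param spikes A [spike_record()].
#' @param path File path.
#' @return `read_spike_record()` returns the [spike_record()].
#' @export
write_spike_record <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_record"))
  write_header(path, list(n_e = spikes$n_e, n_i = spikes$n_i,
                          duration_ms = spikes$duration_ms,
                          dt_ms = spikes$dt_ms))
  append_table(spikes$events, path)
  invisible(path)
}

#' @rdname write_spike_record
#' @export
read_spike_record <- function(path) {
  h <- read_header(path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  spike_record(df, n_e = as.integer(h$n_e), n_i = as.integer(h$n_i),
               duration_ms = as.numeric(h$duration_ms),
               dt_ms = as.numeric(h$dt_ms))
}

#' Write / read a stimulus train
#'
#' Two tab-delimited columns (`time_ms`, `neuron_id`), sorted by time, with
#' the stimulus parameters in the header.
#'
#' @param stim A stimulus train from [generate_stimulus()].
#' @param path File path.
#' @return `read_stimulus_train()` returns the stimulus train.
#' @export
write_stimulus_train <- function(stim, path) {
  stopifnot(inherits(stim, "stimulus_train"))
  sp <- attr(stim, "spec")
  write_header(path, list(period_ms = sp$period_ms, lambda_hz = sp$lambda_hz,
                          window_ms = sp$window_ms,
                          amplitude_mv = sp$amplitude_mv,
                          duration_ms = sp$duration_ms,
                          n_neurons = attr(stim, "n_neurons")))
  append_table(as.data.frame(stim), path)
  invisible(path)
}

#' @rdname write_stimulus_train
#' @export
read_stimulus_train <- function(path) {
  h <- read_header(path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  spec <- stimulus_spec(period_ms = as.numeric(h$period_ms),
                        lambda_hz = as.numeric(h$lambda_hz),
                        window_ms = as.numeric(h$window_ms),
                        amplitude_mv = as.numeric(h$amplitude_mv),
                        duration_ms = as.numeric(h$duration_ms))
  structure(df, class = c("stimulus_train", "data.frame"),
            spec = spec, n_neurons = as.integer(h$n_neurons))
}

#' Write the tables of a spectral summary
#'
#' Writes `spectra.tsv` (`freq_hz`, `psd_mean`, `psd_sd`, `itpc`) and
#' `band_means.tsv` to `dir`.
#'
#' @param summary A `spectral_summary` (see [run_condition()]).
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_spectral_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "spectral_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- data.frame(freq_hz = summary$freq_hz, psd_mean = summary$psd_mean,
                     psd_sd = summary$psd_sd, itpc = summary$itpc$itpc)
  write.table(spec, file.path(dir, "spectra.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(summary$band_means, file.path(dir, "band_means.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

## Persist the artifacts of a finished condition: stimulus, per-trial spike
## records, spectral tables, run manifest (seeds and parameters).
write_condition_result <- function(res, stim, records, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_stimulus_train(stim, file.path(out_dir, "stimulus.tsv"))
  if (!is.null(records))
    for (m in seq_along(records))
      if (!is.null(records[[m]]))
        write_spike_record(records[[m]],
                           file.path(out_dir, sprintf("spikes_trial%02d.tsv", m)))
  if (!is.null(res$summary)) write_spectral_summary(res$summary, out_dir)
  manifest <- c(condition_to_list(res$spec),
                list(trial_seeds = vapply(seq_len(res$spec$n_trials),
                                          function(m) trial_seed(res$spec$base_seed, m),
                                          integer(1)),
                     stimulus_seed = stream_seed(res$spec$base_seed, "stimulus"),
                     stimulus_hash = res$stimulus_hash,
                     trial_status = res$trial_status,
                     package_version = as.character(utils::packageVersion("assrnet"))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
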