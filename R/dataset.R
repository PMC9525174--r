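#' Per-unit, per-trial spike dataset
#'
#' The central data container: a long table of spike times plus optional
#' per-unit metadata (waveforms, light-pulse trials, depths). Spike times are
#' in seconds relative to the onset of the first noise burst of each trial,
#' so baseline spikes have negative times.
#'
#' @param spikes data.frame with columns `unit_id` (character or integer),
#'   `trial_index` (integer, 0-based, in `[0, n_trials)`) and `spike_time_s`
#'   (numeric). Sorted internally by unit, trial, time.
#' @param schedule the [stimulus_schedule()] the spikes were recorded under.
#' @param units optional per-unit metadata data.frame with at least a
#'   `unit_id` column; typical extra columns: `trough_to_peak_us`,
#'   `depth`, `source`. Units present in `spikes` but missing here are added
#'   with NA metadata.
#' @param waveforms optional named list (by unit_id) of lists with elements
#'   `spont` and `light`: mean waveform snippets (numeric vectors) and
#'   `sample_period_us`.
#' @param light_trials optional data.frame (`unit_id`, `trial_index`,
#'   `spike_time_s` relative to light-pulse onset) from an opto-tagging
#'   protocol.
#'
#' @return An object of class `spike_dataset`.
#' @export
spike_dataset <- function(spikes, schedule, units = NULL,
                          waveforms = NULL, light_trials = NULL) {
  stopifnot(is.data.frame(spikes),
            all(c("unit_id", "trial_index", "spike_time_s") %in% names(spikes)),
            inherits(schedule, "stimulus_schedule"))
  spikes$unit_id <- as.character(spikes$unit_id)
  spikes$trial_index <- as.integer(spikes$trial_index)
  if (nrow(spikes) > 0) {
    if (any(spikes$trial_index < 0L | spikes$trial_index >= schedule$n_trials))
      stop("trial_index out of [0, n_trials)")
    spikes <- spikes[order(spikes$unit_id, spikes$trial_index,
                           spikes$spike_time_s), , drop = FALSE]
    rownames(spikes) <- NULL
  }
  ids <- unique(spikes$unit_id)
  if (is.null(units)) {
    units <- data.frame(unit_id = ids, stringsAsFactors = FALSE)
  } else {
    units$unit_id <- as.character(units$unit_id)
    missing <- setdiff(ids, units$unit_id)
    if (length(missing) > 0) {
      pad <- units[rep(NA_integer_, length(missing)), , drop = FALSE]
      pad$unit_id <- missing
      units <- rbind(units, pad)
    }
    rownames(units) <- NULL
  }
  structure(list(spikes = spikes, units = units, schedule = schedule,
                 waveforms = waveforms, light_trials = light_trials),
            class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat(sprintf("Spike dataset: %d units, %d trials, %d spikes\n",
              nrow(x$units), x$schedule$n_trials, nrow(x$spikes)))
  invisible(x)
}

#' Unit ids present in a dataset
#' @param dataset a [spike_dataset()].
#' @return character vector of unit ids (metadata order).
#' @export
unit_ids <- function(dataset) dataset$units$unit_id

.unit_spikes <- function(dataset, unit_id) {
  if (!unit_id %in% dataset$units$unit_id)
    stop(sprintf("unknown unit '%s'", unit_id))
  dataset$spikes[dataset$spikes$unit_id == unit_id, , drop = FALSE]
}

#' Read / write the delimited spike-table format
#'
#' Plain tab-delimited text with a header line and columns `unit_id`,
#' `trial_index`, `spike_time_s`. `write_spikes()` writes that table from a
#' dataset; `read_spikes()` reads one back into a [spike_dataset()] under a
#' given schedule.
#'
#' @param dataset a [spike_dataset()].
#' @param path file path.
#' @param schedule schedule to attach on read.
#' @return `read_spikes()` returns a [spike_dataset()]; `write_spikes()`
#'   returns `path` invisibly.
#' @export
write_spikes <- function(dataset, path) {
  utils::write.table(dataset$spikes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path, schedule) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "integer", "numeric"),
                           stringsAsFactors = FALSE)
  spike_dataset(tab, schedule)
}

#' Spontaneous firing rate of a unit
#'
#' Total baseline spike count divided by total baseline time, where the
#' baseline is the `baseline_dur` seconds immediately preceding the first
#' burst on every trial.
#'
#' @param dataset a [spike_dataset()].
#' @param unit_id unit to measure.
#' @return rate in Hz.
#' @export
spontaneous_rate <- function(dataset, unit_id) {
  sch <- dataset$schedule
  sp <- .unit_spikes(dataset, unit_id)
  n_base <- sum(sp$spike_time_s >= -sch$baseline_dur & sp$spike_time_s < 0)
  n_base / (sch$baseline_dur * sch$n_trials)
}
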