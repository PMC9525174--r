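# PSTH construction, baseline statistics, z-scoring and normalization.
#
# Rates are expressed throughout in spikes/bin/trial: the trial-averaged
# spike count per time bin. All bins are half-open [t, t + bin); a spike
# exactly at a burst onset therefore belongs to the first in-burst bin.

#' Low-level PSTH constructor
#'
#' Builds a `psth` object from a raw rate vector. Normally produced by
#' [build_psth()]; exposed so that tests and callers can construct PSTHs with
#' exactly known values.
#'
#' @param rate numeric vector, spikes/bin/trial per bin (raw view, >= 0).
#' @param bin_edges numeric vector of length `length(rate) + 1`, seconds.
#' @param baseline_mean,baseline_sd baseline statistics in spikes/bin/trial
#'   (may be `NA` until [baseline_stats()] has been applied).
#' @param n_trials number of trials averaged over.
#' @return object of class `psth` with fields `rate`, `bin_edges`,
#'   `baseline_mean`, `baseline_sd`, `n_trials`, and (after
#'   [zscore_and_normalize()]) `zscored` and `normalized` views.
#' @export
psth <- function(rate, bin_edges, baseline_mean = NA_real_,
                 baseline_sd = NA_real_, n_trials = NA_integer_) {
  stopifnot(length(bin_edges) == length(rate) + 1L, all(diff(bin_edges) > 0))
  if (any(rate < 0)) stop("raw PSTH rate must be non-negative")
  structure(list(rate = as.numeric(rate), bin_edges = as.numeric(bin_edges),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 n_trials = n_trials, zscored = NULL, normalized = NULL),
            class = "psth")
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("PSTH: %d bins of %.1f ms over [%.3f, %.3f] s; peak %.3f spk/bin/trial\n",
              length(x$rate), 1000 * diff(x$bin_edges[1:2]),
              x$bin_edges[1], x$bin_edges[length(x$bin_edges)],
              max(x$rate)))
  invisible(x)
}

# Per-trial binned spike-count matrix (n_trials x n_bins) for one unit over
# [span[1], span[2]) at bin width bin_s. Shared by build_psth() and the
# reliability machinery, where the same matrix is resampled many times.
.trial_bin_matrix <- function(dataset, unit_id, bin_s, span) {
  sch <- dataset$schedule
  sp <- .unit_spikes(dataset, unit_id)
  n_bins <- as.integer(round((span[2] - span[1]) / bin_s))
  if (abs(n_bins * bin_s - (span[2] - span[1])) > bin_s)
    stop("bin_s does not divide the analysis span")
  keep <- sp$spike_time_s >= span[1] & sp$spike_time_s < span[1] + n_bins * bin_s
  t <- sp$spike_time_s[keep]
  tr <- sp$trial_index[keep]
  bin <- pmin(floor((t - span[1]) / bin_s), n_bins - 1L)
  counts <- tabulate(tr * n_bins + bin + 1L, nbins = sch$n_trials * n_bins)
  matrix(counts, nrow = sch$n_trials, ncol = n_bins, byrow = TRUE)
}

#' Build a raw PSTH for one unit
#'
#' Bins spikes over the analysis span (`analysis_start` to `analysis_end` of
#' the schedule) and averages counts over trials, giving spikes/bin/trial.
#'
#' @param dataset a [spike_dataset()].
#' @param unit_id unit to analyse.
#' @param schedule optional [stimulus_schedule()]; defaults to the dataset's.
#' @param bin_s bin width in seconds (default 0.010).
#' @return a [psth()] (raw view only; attach baseline with
#'   [zscore_and_normalize()]).
#' @export
build_psth <- function(dataset, unit_id, schedule = dataset$schedule,
                       bin_s = 0.010) {
  if (schedule$n_trials < 1) stop("zero trials")
  span <- c(schedule$analysis_start, schedule$analysis_end)
  M <- .trial_bin_matrix(dataset, unit_id, bin_s, span)
  n_bins <- ncol(M)
  psth(colSums(M) / schedule$n_trials,
       bin_edges = span[1] + bin_s * (0:n_bins),
       n_trials = schedule$n_trials)
}

#' Baseline mean and SD of spontaneous firing
#'
#' Bins the `baseline_dur` seconds preceding the first burst at the same bin
#' width as the response PSTH, averages over trials, and returns the mean and
#' SD across baseline time bins of that trial-averaged trace (the reference
#' used for z-scoring and the detection thresholds).
#'
#' @inheritParams build_psth
#' @return list with `baseline_mean` and `baseline_sd` (spikes/bin/trial).
#' @export
baseline_stats <- function(dataset, unit_id, schedule = dataset$schedule,
                           bin_s = 0.010) {
  if (schedule$iti < schedule$baseline_dur)
    stop("insufficient baseline: inter-trial interval shorter than baseline_dur")
  span <- c(-schedule$baseline_dur, 0)
  M <- .trial_bin_matrix(dataset, unit_id, bin_s, span)
  trace <- colSums(M) / schedule$n_trials
  list(baseline_mean = mean(trace), baseline_sd = stats::sd(trace))
}

#' Attach z-scored and normalized views to a PSTH
#'
#' The z-scored view is `(raw - baseline_mean) / baseline_sd`; the normalized
#' view divides the z-scored PSTH by its absolute maximum, so the normalized
#' view has `max(abs(.)) == 1` whenever the z-scored view is not identically
#' zero. A degenerate baseline (`baseline_sd == 0`) is an error unless
#' `sd_floor` is supplied (e.g. the one-spike-in-all-trials equivalent
#' `1 / n_trials`).
#'
#' @param x a [psth()].
#' @param baseline list from [baseline_stats()].
#' @param sd_floor optional lower bound substituted for a zero baseline SD.
#' @return the PSTH with `baseline_mean`, `baseline_sd`, `zscored` and
#'   `normalized` fields filled.
#' @export
zscore_and_normalize <- function(x, baseline, sd_floor = NULL) {
  stopifnot(inherits(x, "psth"))
  bm <- baseline$baseline_mean
  bs <- baseline$baseline_sd
  if (is.na(bs) || bs == 0) {
    if (is.null(sd_floor)) stop("degenerate baseline (SD = 0)")
    bs <- max(bs, sd_floor, na.rm = TRUE)
  }
  z <- (x$rate - bm) / bs
  m <- max(abs(z))
  x$baseline_mean <- bm
  x$baseline_sd <- bs
  x$zscored <- z
  x$normalized <- if (m > 0) z / m else z
  x
}

#' Event-aligned onset latency
#'
#' Builds an event-aligned PSTH at 2 ms bins, smooths it with a third-order
#' Savitzky-Golay filter over a 10 ms (5-point) window, and reports the left
#' edge of the first post-event bin whose smoothed rate exceeds the baseline
#' mean by 2.5 baseline SDs. Baseline statistics come from the 100 ms of
#' activity preceding each event.
#'
#' @param dataset a [spike_dataset()].
#' @param unit_id unit to analyse.
#' @param event_times numeric vector of event (e.g. tone or light-pulse
#'   onset) times on the same clock as the spike times; with per-trial
#'   event-relative spikes (e.g. light trials), use `event_times = 0` and it
#'   is applied within every trial.
#' @param response_dur length of the post-event span searched, seconds
#'   (default 0.100).
#' @param bin_s bin width (default 0.002 s).
#' @param baseline_dur pre-event baseline span (default 0.100 s).
#' @return latency in ms, or `NA_real_` if no bin crosses threshold.
#' @export
onset_latency <- function(dataset, unit_id, event_times = 0,
                          response_dur = 0.100, bin_s = 0.002,
                          baseline_dur = 0.100) {
  sp <- .unit_spikes(dataset, unit_id)
  # fold spikes around each event
  rel <- unlist(lapply(event_times, function(e) sp$spike_time_s - e),
                use.names = FALSE)
  n_events <- length(event_times) * dataset$schedule$n_trials
  latency_from_rel_times(rel, n_events, response_dur = response_dur,
                         bin_s = bin_s, baseline_dur = baseline_dur)
}

#' Latency from event-relative spike times
#'
#' Workhorse behind [onset_latency()], usable directly when spike times are
#' already event-aligned (e.g. opto-tagging trials).
#'
#' @param rel_times spike times relative to event onset, seconds.
#' @param n_events number of event repetitions the times were pooled over.
#' @inheritParams onset_latency
#' @return latency in ms, or `NA_real_`.
#' @export
latency_from_rel_times <- function(rel_times, n_events, response_dur = 0.100,
                                   bin_s = 0.002, baseline_dur = 0.100) {
  stopifnot(n_events >= 1)
  edges <- seq(-baseline_dur, response_dur, by = bin_s)
  keep <- rel_times >= edges[1] & rel_times < edges[length(edges)]
  counts <- if (any(keep)) {
    bin <- floor((rel_times[keep] - edges[1]) / bin_s) + 1L
    tabulate(bin, nbins = length(edges) - 1L)
  } else rep(0L, length(edges) - 1L)
  rate <- counts / n_events
  sm <- signal::sgolayfilt(rate, p = 3, n = 5)
  base_idx <- which(edges[-length(edges)] < 0)
  bmean <- mean(rate[base_idx])
  bsd <- stats::sd(rate[base_idx])
  if (is.na(bsd) || bsd == 0) stop("degenerate latency baseline (SD = 0)")
  post <- which(edges[-length(edges)] >= 0)
  hit <- post[sm[post] > bmean + 2.5 * bsd]
  if (length(hit) == 0) return(NA_real_)
  round(1000 * edges[hit[1]], 6)  # bin edges carry float noise well below 1 ns
}
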