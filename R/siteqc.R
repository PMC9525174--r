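# Recording-site inclusion gates: multiunit threshold crossings, frequency
# tuning tests, primary-like latency, and fractional cortical depth.

#' Detect multiunit threshold crossings in a filtered voltage trace
#'
#' Events are negative excursions of an already bandpassed voltage trace
#' below `median(v) - mad_mult * mad(v)`, using the normal-consistent MAD
#' (`stats::mad`, the robust SD). One event is emitted per sub-threshold
#' excursion: the detector re-arms only after the trace rises back above
#' threshold.
#'
#' @param v numeric voltage trace (pre-filtered, e.g. 300-6000 Hz bandpass).
#' @param fs sampling rate, Hz.
#' @param mad_mult threshold multiplier (default 5).
#' @return event times in seconds (first sample of each excursion).
#' @export
detect_mua_crossings <- function(v, fs, mad_mult = 5) {
  m <- stats::mad(v)
  if (m == 0) stop("flat trace: MAD is zero")
  thr <- stats::median(v) - mad_mult * m
  below <- v < thr
  starts <- which(below & !c(FALSE, below[-length(below)]))
  (starts - 1) / fs
}

#' Frequency-tuning test for one channel
#'
#' A channel is tuned iff (A) the mean evoked rate at the best frequency
#' exceeds 1.5x the mean of the other frequencies' mean rates, and (B) the
#' variance of the mean rates across frequencies exceeds the 99th percentile
#' of a null distribution obtained by shuffling the interspike intervals of
#' every tone presentation and recomputing the tuning-curve variance.
#'
#' @param tone_spikes data.frame (`freq` in 1..n_freq, `rep`, `spike_time_s`
#'   relative to tone onset) covering the presentation epoch
#'   `presentation_span`.
#' @param n_freq number of frequencies (default 14; 4-64 kHz log-spaced).
#' @param n_reps repetitions per frequency.
#' @param evoked_window tone-evoked window, s (default the 100 ms tone).
#' @param presentation_span epoch each presentation's spikes span, s.
#' @param n_null null draws (default 1000).
#' @param seed optional seed for the shuffles.
#' @return list with `tuned`, `criterion_a`, `criterion_b`, `ftc` (mean
#'   evoked rate per frequency, Hz), `variance`, `null_q99`.
#' @export
ftc_tuned <- function(tone_spikes, n_freq = 14L, n_reps,
                      evoked_window = c(0, 0.100),
                      presentation_span = c(-0.100, 0.300),
                      n_null = 1000, seed = NULL) {
  stopifnot(n_reps >= 2)
  if (!is.null(seed)) set.seed(as.integer(seed))
  ew <- evoked_window
  ftc_from <- function(t, freq) {
    inw <- t >= ew[1] & t < ew[2]
    counts <- tabulate(freq[inw], nbins = n_freq)
    counts / (n_reps * diff(ew))
  }
  ftc <- ftc_from(tone_spikes$spike_time_s, tone_spikes$freq)
  best <- which.max(ftc)
  crit_a <- ftc[best] > 1.5 * mean(ftc[-best])
  v_obs <- stats::var(ftc)

  key <- interaction(tone_spikes$freq, tone_spikes$rep, drop = TRUE)
  by_pres <- split(tone_spikes$spike_time_s, key)
  freq_of <- vapply(split(tone_spikes$freq, key), `[`, numeric(1), 1)
  null_v <- vapply(seq_len(n_null), function(b) {
    shuf <- lapply(by_pres, isi_shuffle)
    t_all <- unlist(shuf, use.names = FALSE)
    f_all <- rep.int(freq_of, lengths(shuf))
    stats::var(ftc_from(t_all, f_all))
  }, numeric(1))
  crit_b <- v_obs > stats::quantile(null_v, 0.99, names = FALSE)
  list(tuned = crit_a && crit_b, criterion_a = crit_a, criterion_b = crit_b,
       ftc = ftc, variance = v_obs,
       null_q99 = stats::quantile(null_v, 0.99, names = FALSE))
}

#' Significance of tone-evoked firing for one channel
#'
#' Paired one-sided Wilcoxon signed-rank test of the evoked rate (the 100 ms
#' tone) against the pre-tone baseline rate across tone presentations.
#'
#' @inheritParams ftc_tuned
#' @param baseline_window pre-tone window, s.
#' @return p-value.
#' @export
tone_driven_p <- function(tone_spikes, n_freq = 14L, n_reps,
                          evoked_window = c(0, 0.100),
                          baseline_window = c(-0.100, 0)) {
  key <- interaction(tone_spikes$freq, tone_spikes$rep, drop = TRUE)
  n_pres <- n_freq * n_reps
  count_in <- function(w) {
    inw <- tone_spikes$spike_time_s >= w[1] & tone_spikes$spike_time_s < w[2]
    c(table(factor(key[inw], levels = levels(key))),
      rep(0L, n_pres - nlevels(key)))
  }
  ev <- count_in(evoked_window) / diff(evoked_window)
  ba <- count_in(baseline_window) / diff(baseline_window)
  if (all(ev == ba)) return(1)
  suppressWarnings(stats::wilcox.test(ev, ba, paired = TRUE,
                                      alternative = "greater",
                                      exact = FALSE)$p.value)
}

#' Recording-site inclusion decision
#'
#' A site is included iff, over the channels with significantly elevated
#' tone-evoked firing, the median onset latency is at most
#' `max_median_latency_ms` (primary-like) and at least `min_tuned_frac` of
#' those channels pass the frequency-tuning criteria.
#'
#' @param channels data.frame with per-channel columns `driven` (logical),
#'   `latency_ms`, `tuned` (logical).
#' @param max_median_latency_ms latency gate (default 14).
#' @param min_tuned_frac tuned-fraction gate over driven channels
#'   (default 0.5).
#' @return list with `include`, `reason`, `median_latency_ms`, `tuned_frac`.
#' @export
site_inclusion <- function(channels, max_median_latency_ms = 14,
                           min_tuned_frac = 0.5) {
  driven <- channels[channels$driven, , drop = FALSE]
  if (nrow(driven) == 0)
    return(list(include = FALSE, reason = "no significantly driven channels",
                median_latency_ms = NA_real_, tuned_frac = NA_real_))
  med_lat <- stats::median(driven$latency_ms, na.rm = TRUE)
  tuned_frac <- mean(driven$tuned)
  include <- med_lat <= max_median_latency_ms &&
    tuned_frac >= min_tuned_frac
  reason <- if (include) "included"
            else if (med_lat > max_median_latency_ms)
              "median latency not primary-like"
            else "too few tuned channels"
  list(include = include, reason = reason, median_latency_ms = med_lat,
       tuned_frac = tuned_frac)
}

#' Fractional cortical depth of a channel
#'
#' Linear map of channel index between the shallowest (0) and deepest (1)
#' sound-driven channels.
#'
#' @param channel_index channel to map (may be a vector).
#' @param shallowest_idx,deepest_idx boundary channels
#'   (`shallowest_idx < deepest_idx`).
#' @return fraction(s) in `[0, 1]`.
#' @export
fractional_depth <- function(channel_index, shallowest_idx, deepest_idx) {
  stopifnot(shallowest_idx < deepest_idx)
  if (any(channel_index < shallowest_idx | channel_index > deepest_idx))
    stop("channel outside the shallowest-deepest bounds")
  (channel_index - shallowest_idx) / (deepest_idx - shallowest_idx)
}

#' Bin fractional depths into linearly spaced bins
#'
#' Partitions `[0, 1]` into `n_bins` equal bins (default 7); depth 1 falls in
#' the deepest bin.
#'
#' @param depth fractional depths in `[0, 1]`.
#' @param n_bins number of bins (default 7).
#' @return integer bin index in 1..n_bins.
#' @export
depth_bins <- function(depth, n_bins = 7L) {
  stopifnot(all(depth >= 0 & depth <= 1))
  pmin(floor(depth * n_bins) + 1L, n_bins)
}
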