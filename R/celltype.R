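# Waveform-based narrow-/broad-spiking classification and the four-criterion
# opto-tagging procedure.

#' Trough-to-peak delay of an action-potential waveform
#'
#' Time from the global trough (spike minimum) to the subsequent waveform
#' peak, in microseconds.
#'
#' @param waveform numeric vector (mean waveform snippet).
#' @param sample_period_us sampling period of the snippet, microseconds.
#' @return delay in microseconds.
#' @export
trough_to_peak <- function(waveform, sample_period_us) {
  trough <- which.min(waveform)
  if (which.max(waveform) < trough)
    stop("no trough-peak structure: waveform peak precedes the trough")
  if (trough >= length(waveform))
    stop("no trough-peak structure: trough at end of snippet")
  after <- waveform[(trough + 1L):length(waveform)]
  peak <- trough + which.max(after)
  if (waveform[peak] <= waveform[trough])
    stop("no trough-peak structure: no rise after trough")
  (peak - trough) * sample_period_us
}

#' Narrow- vs broad-spiking classification
#'
#' Units with a trough-to-peak delay below the boundary (default 600 us, the
#' dip of the bimodal delay distribution) are narrow spiking (NS, putative
#' inhibitory); units at or above it are broad spiking (BS, putative
#' excitatory). The boundary itself is assigned BS.
#'
#' @param ttp_us trough-to-peak delay(s), microseconds.
#' @param boundary_us NS/BS boundary (default 600).
#' @return character vector, `"NS"` or `"BS"`.
#' @export
classify_ns_bs <- function(ttp_us, boundary_us = 600) {
  stopifnot(all(ttp_us > 0))
  ifelse(ttp_us < boundary_us, "NS", "BS")
}

#' Opto-tagging criteria defaults
#' @param min_spikes minimum light-evoked and spontaneous spike counts.
#' @param alpha significance level for the firing-elevation test.
#' @param max_latency_ms maximum light-evoked onset latency.
#' @param min_waveform_corr minimum light-evoked vs spontaneous waveform
#'   correlation.
#' @param evoked_window light-evoked response window relative to pulse onset,
#'   s: the 10 ms pulse plus a 15 ms tail, covering sub-5-ms-latency
#'   responses without swallowing rebound firing.
#' @param baseline_window pre-pulse baseline window, s.
#' @return list of settings.
#' @export
tagging_criteria <- function(min_spikes = 10, alpha = 0.01,
                             max_latency_ms = 5, min_waveform_corr = 0.95,
                             evoked_window = c(0, 0.025),
                             baseline_window = c(-0.100, 0)) {
  list(min_spikes = min_spikes, alpha = alpha,
       max_latency_ms = max_latency_ms,
       min_waveform_corr = min_waveform_corr,
       evoked_window = evoked_window, baseline_window = baseline_window)
}

#' Four-criterion opto-tagging of one unit
#'
#' A unit is opto-tagged iff (1) it fired at least `min_spikes` light-evoked
#' and `min_spikes` spontaneous spikes during the protocol, (2) its
#' light-evoked firing is significantly elevated over the pre-pulse baseline
#' (one-sided paired Wilcoxon signed-rank across trials, `p < alpha`),
#' (3) its light-evoked onset latency is at most `max_latency_ms`, and
#' (4) its mean light-evoked and mean spontaneous waveforms correlate at
#' `>= min_waveform_corr` (Pearson). Units with significant elevation
#' (criterion 2) but failing another criterion are `"ambiguous"` and are
#' excluded from downstream NS/BS pools; all other non-tagged units are
#' `"untagged"`.
#'
#' @param light_trials data.frame (`trial_index`, `spike_time_s` relative to
#'   pulse onset) for this unit, or NULL if no light data.
#' @param waveforms list with `spont` and `light` mean waveform vectors, or
#'   NULL.
#' @param n_trials number of light trials in the protocol (default 75).
#' @param criteria list from [tagging_criteria()].
#' @return list with `verdict` (`"tagged"`, `"ambiguous"`, `"untagged"`),
#'   `criteria` (named logical vector: counts, elevation, latency,
#'   waveform_corr), `latency_ms`, `waveform_corr`, `p_elevation`.
#' @export
optotag <- function(light_trials, waveforms, n_trials = 75L,
                    criteria = tagging_criteria()) {
  if (is.null(light_trials) || nrow(light_trials) == 0) {
    return(list(verdict = "untagged",
                criteria = c(counts = NA, elevation = NA, latency = NA,
                             waveform_corr = NA),
                latency_ms = NA_real_, waveform_corr = NA_real_,
                p_elevation = NA_real_))
  }
  ew <- criteria$evoked_window
  bw <- criteria$baseline_window
  t <- light_trials$spike_time_s
  evoked <- t >= ew[1] & t < ew[2]
  # spontaneous = protocol spikes outside the evoked window
  n_evoked <- sum(evoked)
  n_spont <- sum(!evoked)
  c1 <- n_evoked >= criteria$min_spikes && n_spont >= criteria$min_spikes

  # criterion 2: per-trial evoked vs baseline rates, paired one-sided
  trials <- seq_len(n_trials) - 1L
  count_in <- function(w) {
    inw <- t >= w[1] & t < w[2]
    tabulate(match(light_trials$trial_index[inw], trials),
             nbins = n_trials)
  }
  ev_rate <- count_in(ew) / diff(ew)
  ba_rate <- count_in(bw) / diff(bw)
  p2 <- if (all(ev_rate == ba_rate)) 1 else
    suppressWarnings(stats::wilcox.test(ev_rate, ba_rate, paired = TRUE,
                                        alternative = "greater",
                                        exact = FALSE)$p.value)
  c2 <- is.finite(p2) && p2 < criteria$alpha

  lat <- tryCatch(latency_from_rel_times(t, n_trials),
                  error = function(e) NA_real_)
  c3 <- !is.na(lat) && lat <= criteria$max_latency_ms

  wcor <- if (!is.null(waveforms) && !is.null(waveforms$spont) &&
              !is.null(waveforms$light))
    stats::cor(waveforms$spont, waveforms$light) else NA_real_
  c4 <- !is.na(wcor) && wcor >= criteria$min_waveform_corr

  crit <- c(counts = c1, elevation = c2, latency = c3, waveform_corr = c4)
  verdict <- if (all(crit)) "tagged"
             else if (c2) "ambiguous"
             else "untagged"
  list(verdict = verdict, criteria = crit, latency_ms = lat,
       waveform_corr = wcor, p_elevation = p2)
}

#' Build unit profiles: cell class, opto-tag verdict, spontaneous rate
#'
#' @param dataset a [spike_dataset()] whose `units` table has
#'   `trough_to_peak_us` (or whose `waveforms` carry snippets to measure it
#'   from), plus optional `light_trials` and `waveforms` for tagging.
#' @param n_light_trials number of light-pulse trials (default 75).
#' @param criteria list from [tagging_criteria()].
#' @param boundary_us NS/BS boundary (default 600).
#' @return data.frame (`unit_id`, `trough_to_peak_us`, `cell_class`,
#'   `tag_verdict`, `spont_rate_hz`, `depth`).
#' @export
unit_profiles <- function(dataset, n_light_trials = 75L,
                          criteria = tagging_criteria(),
                          boundary_us = 600) {
  ids <- unit_ids(dataset)
  ttp <- if ("trough_to_peak_us" %in% names(dataset$units))
    dataset$units$trough_to_peak_us
  else if (!is.null(dataset$waveforms)) vapply(ids, function(u) {
    wf <- dataset$waveforms[[u]]
    trough_to_peak(wf$spont, wf$sample_period_us)
  }, numeric(1))
  else rep(NA_real_, length(ids))
  verdict <- vapply(ids, function(u) {
    lt <- dataset$light_trials
    lt <- if (is.null(lt)) NULL else lt[lt$unit_id == u, , drop = FALSE]
    optotag(lt, dataset$waveforms[[u]], n_trials = n_light_trials,
            criteria = criteria)$verdict
  }, character(1))
  data.frame(
    unit_id = ids, trough_to_peak_us = ttp,
    cell_class = if (all(is.na(ttp))) rep(NA_character_, length(ids))
                 else classify_ns_bs(ttp, boundary_us),
    tag_verdict = verdict,
    spont_rate_hz = vapply(ids, spontaneous_rate, numeric(1),
                           dataset = dataset),
    depth = if ("depth" %in% names(dataset$units)) dataset$units$depth
            else NA_real_,
    stringsAsFactors = FALSE, row.names = NULL)
}
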