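#' Stimulus schedule for a repeated noise-burst protocol
#'
#' Describes the timing of the history-dependence stimulus: `n_bursts` noise
#' bursts of `burst_dur` seconds separated by silent gaps of `gap_dur`
#' seconds, presented for `n_trials` trials, with at least `baseline_dur`
#' seconds of spontaneous activity recorded before the first burst on every
#' trial. All analysis windows (PSTH span, onset/offset response windows,
#' baseline window) are derived from this object. Times are in seconds,
#' relative to the onset of the first noise burst (t = 0).
#'
#' @param n_bursts number of noise bursts per trial (default 4).
#' @param burst_dur duration of each noise burst in seconds (default 0.150).
#' @param gap_dur duration of the silent gap after each burst, seconds
#'   (default 0.150). The offset response window of burst k is the gap that
#'   follows it.
#' @param n_trials number of stimulus presentations (default 120).
#' @param baseline_dur duration of pre-stimulus spontaneous activity used for
#'   baseline statistics, seconds (default 4).
#' @param iti inter-trial interval in seconds (default 4.5; must leave room
#'   for the baseline).
#' @param analysis_start start of the PSTH analysis span relative to the
#'   first burst onset, seconds (default -0.200).
#'
#' @return An object of class `stimulus_schedule`: a list with the fields
#'   above plus `stim_end` (end of the last burst) and `analysis_end`
#'   (`stim_end + gap_dur`, i.e. 150 ms past the last burst by default).
#' @export
#' @examples
#' sch <- stimulus_schedule()
#' sch$analysis_end  # 1.2 s for the default 4 x 150 ms bursts
stimulus_schedule <- function(n_bursts = 4L, burst_dur = 0.150,
                              gap_dur = 0.150, n_trials = 120L,
                              baseline_dur = 4.0, iti = 4.5,
                              analysis_start = -0.200) {
  stopifnot(n_bursts >= 1, burst_dur > 0, gap_dur > 0, n_trials >= 1,
            baseline_dur > 0, iti > 0)
  if (analysis_start >= 0)
    stop("analysis_start must be negative (span begins before the stimulus)")
  stim_end <- n_bursts * burst_dur + (n_bursts - 1) * gap_dur
  out <- list(
    n_bursts = as.integer(n_bursts), burst_dur = burst_dur,
    gap_dur = gap_dur, n_trials = as.integer(n_trials),
    baseline_dur = baseline_dur, iti = iti,
    analysis_start = analysis_start,
    stim_end = stim_end,
    analysis_end = stim_end + gap_dur
  )
  class(out) <- "stimulus_schedule"
  out
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf(
    "Stimulus schedule: %d x %.0f ms bursts, %.0f ms gaps, %d trials\n",
    x$n_bursts, 1000 * x$burst_dur, 1000 * x$gap_dur, x$n_trials))
  cat(sprintf("  analysis span [%.3f, %.3f] s, baseline %.1f s, ITI %.1f s\n",
              x$analysis_start, x$analysis_end, x$baseline_dur, x$iti))
  invisible(x)
}

#' Onset times of each noise burst
#' @param schedule a [stimulus_schedule()].
#' @return numeric vector of burst onset times (s), first burst at 0.
#' @export
burst_onsets <- function(schedule) {
  (seq_len(schedule$n_bursts) - 1) * (schedule$burst_dur + schedule$gap_dur)
}
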