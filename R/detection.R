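# Onset/offset response windows, the three-threshold unambiguous-response
# test, and response magnitudes under the different subtraction methods.

#' Default detection thresholds
#'
#' The three gates of the unambiguous-response test: an absolute excess over
#' baseline (0.025 spikes/bin/trial), a z-score gate (3 baseline SDs), and a
#' prior-firing gate (3x the mean rate in the 50 ms preceding the window).
#'
#' @param abs absolute excess threshold, spikes/bin/trial.
#' @param z z-score threshold.
#' @param prior_mult prior-rate multiplier.
#' @return list of thresholds.
#' @export
detection_thresholds <- function(abs = 0.025, z = 3, prior_mult = 3) {
  list(abs = abs, z = z, prior_mult = prior_mult)
}

#' Build onset and offset response windows from a schedule
#'
#' One onset window per burst (the burst itself) and one offset window per
#' burst (the silence following it); together these tile the span from the
#' first burst onset to `gap_dur` past the last burst. Each window carries a
#' 50 ms `prior` window immediately preceding its start (for the first onset
#' window this is the last 50 ms of the pre-stimulus span, where it reduces
#' to baseline). With `early_late = TRUE`, 0-50 ms ("early") and 100-150 ms
#' ("late") sub-windows of each full window are appended.
#'
#' @param schedule a [stimulus_schedule()].
#' @param early_late also emit early/late sub-windows (default FALSE).
#' @return data.frame (`kind`, `index`, `part` in full/early/late, `start`,
#'   `end`, `prior_start`, `prior_end`), times in seconds.
#' @export
make_windows <- function(schedule, early_late = FALSE) {
  onsets <- burst_onsets(schedule)
  rows <- list()
  for (k in seq_len(schedule$n_bursts)) {
    on_start <- onsets[k]
    off_start <- on_start + schedule$burst_dur
    rows[[length(rows) + 1]] <- data.frame(
      kind = c("onset", "offset"), index = k, part = "full",
      start = c(on_start, off_start),
      end = c(off_start, off_start + schedule$gap_dur),
      stringsAsFactors = FALSE)
  }
  win <- do.call(rbind, rows)
  if (early_late) {
    sub <- win
    early <- transform(sub, part = "early", end = start + 0.050)
    late <- transform(sub, part = "late", start = start + 0.100)
    win <- rbind(win, early, late)
  }
  win$prior_start <- win$start - 0.050
  win$prior_end <- win$start
  win[order(win$part != "full", win$index, win$kind != "onset"), ,
      drop = FALSE] -> win
  rownames(win) <- NULL
  win
}

# bin indices of a psth falling in [start, end)
.bins_in <- function(x, start, end) {
  lo <- x$bin_edges[-length(x$bin_edges)]
  which(lo >= start - 1e-9 & lo < end - 1e-9)
}

# mean raw rate over the prior window of `win` (one row)
.prior_fr <- function(x, win) {
  idx <- .bins_in(x, win$prior_start, win$prior_end)
  if (length(idx) == 0) stop("prior window outside PSTH span")
  mean(x$rate[idx])
}

#' Apply the three-threshold response test to one window
#'
#' A window contains an unambiguous response iff the maximal raw rate in the
#' window (i) exceeds `baseline_mean + abs`, (ii) has a z-score above `z`,
#' and (iii) exceeds `prior_mult` times the mean rate of the 50 ms prior
#' window. When the prior rate is zero the third gate is vacuous (there is no
#' lingering firing to exclude) and is deemed passed.
#'
#' @param x a [psth()] with z-scored view attached
#'   ([zscore_and_normalize()]).
#' @param win one row of [make_windows()].
#' @param thresholds list from [detection_thresholds()].
#' @return one-row data.frame (`kind`, `index`, `part`, `max_rate`, `max_z`,
#'   `prior_fr`, `detected`, plus the three per-gate verdicts).
#' @export
detect_response <- function(x, win, thresholds = detection_thresholds()) {
  stopifnot(inherits(x, "psth"), !is.null(x$zscored))
  idx <- .bins_in(x, win$start, win$end)
  if (length(idx) == 0) stop("window outside PSTH span")
  # earliest bin wins ties (reporting only; detection uses the value)
  max_rate <- max(x$rate[idx])
  max_z <- max(x$zscored[idx])
  prior_fr <- .prior_fr(x, win)
  gate_abs <- max_rate > x$baseline_mean + thresholds$abs
  gate_z <- max_z > thresholds$z
  gate_prior <- prior_fr <= 0 || max_rate > thresholds$prior_mult * prior_fr
  data.frame(kind = win$kind, index = win$index, part = win$part,
             max_rate = max_rate, max_z = max_z, prior_fr = prior_fr,
             gate_abs = gate_abs, gate_z = gate_z, gate_prior = gate_prior,
             detected = gate_abs && gate_z && gate_prior,
             stringsAsFactors = FALSE)
}

#' Response magnitude in a window under a subtraction method
#'
#' `minus_prior` subtracts the mean prior-window rate from the maximal rate;
#' `minus_baseline` subtracts the baseline mean from the maximal rate; `auc`
#' sums the prior-subtracted rate over every bin of the window. All may be
#' negative. Units are spikes/trial.
#'
#' @inheritParams detect_response
#' @param method one of `"minus_prior"`, `"minus_baseline"`, `"auc"`.
#' @return numeric magnitude.
#' @export
measure_magnitude <- function(x, win,
                              method = c("minus_prior", "minus_baseline",
                                         "auc")) {
  method <- match.arg(method)
  idx <- .bins_in(x, win$start, win$end)
  if (length(idx) == 0) stop("window outside PSTH span")
  prior_fr <- .prior_fr(x, win)
  switch(method,
         minus_prior = max(x$rate[idx]) - prior_fr,
         minus_baseline = max(x$rate[idx]) - x$baseline_mean,
         auc = sum(x$rate[idx] - prior_fr))
}

#' Detect responses in all windows of a unit's PSTH
#'
#' Runs [detect_response()] and [measure_magnitude()] (all three methods)
#' over every window.
#'
#' @inheritParams detect_response
#' @param windows data.frame from [make_windows()].
#' @return data.frame with one row per window: detection columns plus
#'   `mag_minus_prior`, `mag_minus_baseline`, `mag_auc`.
#' @export
detect_all_windows <- function(x, windows,
                               thresholds = detection_thresholds()) {
  res <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, , drop = FALSE]
    d <- detect_response(x, w, thresholds)
    d$mag_minus_prior <- measure_magnitude(x, w, "minus_prior")
    d$mag_minus_baseline <- measure_magnitude(x, w, "minus_baseline")
    d$mag_auc <- measure_magnitude(x, w, "auc")
    d
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Classify a unit's responsiveness from its window detections
#'
#' Onset-responsive iff at least one full onset window contains a detected
#' response; offset-responsive analogously.
#'
#' @param measures data.frame from [detect_all_windows()] (full windows).
#' @return one of `"onset_only"`, `"offset_only"`, `"both"`, `"neither"`.
#' @export
classify_responsiveness <- function(measures) {
  full <- measures[measures$part == "full", , drop = FALSE]
  on <- any(full$detected[full$kind == "onset"])
  off <- any(full$detected[full$kind == "offset"])
  if (on && off) "both" else if (on) "onset_only" else if (off) "offset_only"
  else "neither"
}
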