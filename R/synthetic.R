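# Seeded synthetic spike-train generator.
#
# Units are inhomogeneous Poisson processes: a homogeneous spontaneous rate
# plus additive response kernels at each burst onset and offset, scaled by a
# deterministic per-repetition gain (so the expected facilitation-depression
# index has the closed form (f4 - f1) / max(f)). Spikes are drawn exactly by
# superposition: spontaneous spikes are homogeneous Poisson over the whole
# trial, and each response contributes a Poisson number of spikes with times
# drawn from the kernel density (inverse CDF). Sound-suppressed units are
# instead produced by thinning spontaneous spikes during the bursts.

#' Define a unit archetype for the generator
#'
#' @param name archetype label, one of `transient_depressing`,
#'   `sustained_facilitating`, `offset_only`, `onset_and_offset`,
#'   `suppressed`, `unresponsive`.
#' @param spont_rate spontaneous rate, Hz.
#' @param onset_amp,offset_amp peak added rate of the onset/offset response
#'   kernel, Hz (0 = no response).
#' @param onset_kernel,offset_kernel list(shape = "exp"|"box", tau_ms =
#'   decay time constant for "exp"). The kernel spans one burst (onset) or
#'   one gap (offset) window and has unit peak.
#' @param per_rep_factor_onset,per_rep_factor_offset multiplicative gain per
#'   repetition (length `n_bursts`, first element 1: the first repetition is
#'   the reference).
#' @param suppress_gain for the `suppressed` archetype: multiplicative gain
#'   (< 1) applied to the spontaneous rate during each burst.
#' @param trough_to_peak_us waveform trough-to-peak delay, microseconds.
#' @param is_optotagged logical; does the unit respond directly to light.
#' @param light_latency_ms light-evoked firing latency for tagged units, ms.
#' @param depth fractional cortical depth in `[0, 1]`, or `NA` to draw one
#'   uniformly per unit.
#' @param dispersion Fano-factor-like trial-to-trial rate dispersion: each
#'   trial's whole rate profile is multiplied by a Gamma(1/dispersion,
#'   mean 1) gain. 0 (default) gives a pure Poisson process; typical
#'   noise-burst protocols do not constrain this quantity, so it is exposed
#'   as a knob rather than fixed.
#' @return list of class `unit_archetype`.
#' @export
unit_archetype <- function(name, spont_rate = 2,
                           onset_amp = 0, offset_amp = 0,
                           onset_kernel = list(shape = "exp", tau_ms = 20),
                           offset_kernel = list(shape = "exp", tau_ms = 20),
                           per_rep_factor_onset = c(1, 1, 1, 1),
                           per_rep_factor_offset = c(1, 1, 1, 1),
                           suppress_gain = NA_real_,
                           trough_to_peak_us = 800,
                           is_optotagged = FALSE, light_latency_ms = 3,
                           depth = NA_real_, dispersion = 0) {
  stopifnot(spont_rate >= 0, onset_amp >= 0, offset_amp >= 0,
            all(per_rep_factor_onset >= 0), all(per_rep_factor_offset >= 0),
            per_rep_factor_onset[1] == 1, per_rep_factor_offset[1] == 1,
            dispersion >= 0)
  if (name == "unresponsive" && (onset_amp > 0 || offset_amp > 0))
    stop("unresponsive archetype must have zero response amplitudes")
  if (name == "suppressed" && (is.na(suppress_gain) || suppress_gain >= 1))
    stop("suppressed archetype needs suppress_gain < 1")
  structure(list(name = name, spont_rate = spont_rate,
                 onset_amp = onset_amp, offset_amp = offset_amp,
                 onset_kernel = onset_kernel, offset_kernel = offset_kernel,
                 per_rep_factor_onset = per_rep_factor_onset,
                 per_rep_factor_offset = per_rep_factor_offset,
                 suppress_gain = suppress_gain,
                 trough_to_peak_us = trough_to_peak_us,
                 is_optotagged = is_optotagged,
                 light_latency_ms = light_latency_ms,
                 depth = depth, dispersion = dispersion),
            class = "unit_archetype")
}

#' Default archetype library
#'
#' Six response archetypes emulating the main response patterns seen in
#' awake auditory cortex under repeated noise bursts: transient depressing
#' onsets (PV-like narrow spiking), sustained facilitating onsets (SST-like),
#' offset-only units, units with both onset and offset responses, units whose
#' spontaneous firing is suppressed by sound, and unresponsive units.
#'
#' @return named list of [unit_archetype()] objects.
#' @export
default_archetypes <- function() {
  list(
    transient_depressing = unit_archetype(
      "transient_depressing", spont_rate = 2, onset_amp = 120,
      onset_kernel = list(shape = "exp", tau_ms = 20),
      per_rep_factor_onset = c(1, 0.8, 0.65, 0.5),
      trough_to_peak_us = 350, is_optotagged = FALSE),
    sustained_facilitating = unit_archetype(
      "sustained_facilitating", spont_rate = 5, onset_amp = 25,
      onset_kernel = list(shape = "box"),
      per_rep_factor_onset = c(1, 1.1, 1.25, 1.4),
      trough_to_peak_us = 450),
    offset_only = unit_archetype(
      "offset_only", spont_rate = 2, offset_amp = 80,
      offset_kernel = list(shape = "exp", tau_ms = 20),
      per_rep_factor_offset = c(1, 1, 1.05, 1.1),
      trough_to_peak_us = 800),
    onset_and_offset = unit_archetype(
      "onset_and_offset", spont_rate = 10, onset_amp = 100,
      per_rep_factor_onset = c(1, 0.85, 0.7, 0.6),
      offset_amp = 60, per_rep_factor_offset = c(1, 1, 1, 1),
      trough_to_peak_us = 350, is_optotagged = TRUE),
    suppressed = unit_archetype(
      "suppressed", spont_rate = 12, suppress_gain = 0.15,
      trough_to_peak_us = 900),
    unresponsive = unit_archetype(
      "unresponsive", spont_rate = 3, trough_to_peak_us = 700)
  )
}

# kernel integral (s) over a window of length w_s, unit peak
.kernel_integral <- function(kernel, w_s) {
  if (kernel$shape == "box") return(w_s)
  if (kernel$shape == "exp") {
    tau <- kernel$tau_ms / 1000
    return(tau * (1 - exp(-w_s / tau)))
  }
  stop(sprintf("unknown kernel shape '%s'", kernel$shape))
}

# n draws from the normalized kernel density on [0, w_s]
.kernel_sample <- function(kernel, w_s, n) {
  if (n == 0) return(numeric(0))
  u <- stats::runif(n)
  if (kernel$shape == "box") return(u * w_s)
  tau <- kernel$tau_ms / 1000
  -tau * log(1 - u * (1 - exp(-w_s / tau)))
}

.expected_fdi <- function(f) (f[4] - f[1]) / max(f)

#' Generate a seeded spike dataset with known ground truth
#'
#' @param archetype_mix named integer vector: archetype name -> unit count.
#'   Names must exist in `archetypes`.
#' @param schedule a [stimulus_schedule()].
#' @param seed integer seed; identical `(archetype_mix, schedule, seed)`
#'   yields an identical dataset.
#' @param archetypes archetype library (default [default_archetypes()]);
#'   entries may be replaced to plant custom gains or amplitudes.
#' @return list with `dataset` (a [spike_dataset()]) and `ground_truth`
#'   (data.frame: `unit_id`, `archetype`, `expected_fdi_onset`,
#'   `expected_fdi_offset`, `cell_class`, `is_optotagged`, `depth`,
#'   `spont_rate`).
#' @export
generate_dataset <- function(archetype_mix, schedule = stimulus_schedule(),
                             seed = 1L, archetypes = default_archetypes()) {
  archetype_mix <- archetype_mix[archetype_mix > 0]
  if (length(archetype_mix) == 0) stop("no units requested")
  if (is.null(names(archetype_mix)) ||
      !all(names(archetype_mix) %in% names(archetypes)))
    stop("archetype_mix names must match the archetype library")
  set.seed(as.integer(seed))
  sch <- schedule
  t0 <- -(sch$baseline_dur + abs(sch$analysis_start))
  t1 <- sch$analysis_end
  onsets <- burst_onsets(sch)
  arch_of_unit <- rep(names(archetype_mix), archetype_mix)
  n_units <- length(arch_of_unit)
  ids <- sprintf("u%04d", seq_len(n_units))

  spike_list <- vector("list", n_units)
  gt <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    a <- archetypes[[arch_of_unit[i]]]
    ntr <- sch$n_trials
    gain <- if (a$dispersion > 0)
      stats::rgamma(ntr, shape = 1 / a$dispersion, scale = a$dispersion)
    else rep(1, ntr)

    # spontaneous: homogeneous Poisson over the whole trial
    n_sp <- stats::rpois(ntr, a$spont_rate * (t1 - t0) * gain)
    tr <- rep.int(seq_len(ntr) - 1L, n_sp)
    tt <- stats::runif(sum(n_sp), t0, t1)

    if (a$name == "suppressed") {
      # thin spontaneous spikes inside each burst window
      f <- a$per_rep_factor_onset
      for (k in seq_len(sch$n_bursts)) {
        keep_p <- min(1, a$suppress_gain * f[k])
        inb <- tt >= onsets[k] & tt < onsets[k] + sch$burst_dur
        drop <- inb & stats::runif(length(tt)) > keep_p
        tr <- tr[!drop]; tt <- tt[!drop]
      }
    } else {
      for (k in seq_len(sch$n_bursts)) {
        if (a$onset_amp > 0) {
          mu <- a$onset_amp * a$per_rep_factor_onset[k] *
            .kernel_integral(a$onset_kernel, sch$burst_dur)
          n_ev <- stats::rpois(ntr, mu * gain)
          tr <- c(tr, rep.int(seq_len(ntr) - 1L, n_ev))
          tt <- c(tt, onsets[k] +
                    .kernel_sample(a$onset_kernel, sch$burst_dur, sum(n_ev)))
        }
        if (a$offset_amp > 0) {
          mu <- a$offset_amp * a$per_rep_factor_offset[k] *
            .kernel_integral(a$offset_kernel, sch$gap_dur)
          n_ev <- stats::rpois(ntr, mu * gain)
          tr <- c(tr, rep.int(seq_len(ntr) - 1L, n_ev))
          tt <- c(tt, onsets[k] + sch$burst_dur +
                    .kernel_sample(a$offset_kernel, sch$gap_dur, sum(n_ev)))
        }
      }
    }
    spike_list[[i]] <- data.frame(unit_id = ids[i], trial_index = tr,
                                  spike_time_s = tt,
                                  stringsAsFactors = FALSE)
    depth <- if (is.na(a$depth)) stats::runif(1) else a$depth
    gt[[i]] <- data.frame(
      unit_id = ids[i], archetype = a$name,
      expected_fdi_onset = if (a$onset_amp > 0)
        .expected_fdi(a$per_rep_factor_onset) else NA_real_,
      expected_fdi_offset = if (a$offset_amp > 0)
        .expected_fdi(a$per_rep_factor_offset) else NA_real_,
      cell_class = if (a$trough_to_peak_us < 600) "NS" else "BS",
      is_optotagged = a$is_optotagged,
      depth = depth, spont_rate = a$spont_rate,
      trough_to_peak_us = a$trough_to_peak_us,
      light_latency_ms = a$light_latency_ms,
      stringsAsFactors = FALSE)
  }
  spikes <- do.call(rbind, spike_list)
  ground_truth <- do.call(rbind, gt)
  units <- ground_truth[, c("unit_id", "archetype", "cell_class",
                            "is_optotagged", "depth", "trough_to_peak_us",
                            "light_latency_ms")]
  ds <- spike_dataset(spikes, sch, units = units)
  list(dataset = ds, ground_truth = ground_truth)
}

#' Write the per-unit ground-truth table
#' @param ground_truth data.frame from [generate_dataset()].
#' @param path file path (tab-delimited text with header).
#' @export
write_ground_truth <- function(ground_truth, path) {
  utils::write.table(ground_truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# canonical biphasic waveform: unit-amplitude trough at t = 0, positive peak
# at t = trough_to_peak_us; sampled from -330 to 570 us
.waveform_template <- function(trough_to_peak_us, sample_period_us = 10,
                               trough_width_us = 80,
                               span_us = c(-330, 570)) {
  t <- seq(span_us[1], span_us[2], by = sample_period_us)
  peak_width <- 0.45 * trough_to_peak_us
  w <- -exp(-0.5 * (t / trough_width_us)^2) +
    0.5 * exp(-0.5 * ((t - trough_to_peak_us) / peak_width)^2)
  list(t_us = t, w = w)
}

#' Generate mean spontaneous and light-evoked waveform snippets
#'
#' Produces, per unit, a mean spontaneous and a mean light-evoked waveform
#' over -330 to 570 microseconds around the trough: a canonical biphasic
#' template time-scaled to the unit's trough-to-peak delay, plus seeded
#' noise. For units listed in `artifact_units`, the light-evoked waveform is
#' a broadened, shifted shape so that its correlation with the spontaneous
#' waveform falls below the opto-tagging identity criterion.
#'
#' @param units data.frame with `unit_id` and `trough_to_peak_us`.
#' @param seed integer seed.
#' @param sample_period_us waveform sampling period (default 10 us).
#' @param noise_sd SD of additive noise relative to unit trough amplitude.
#' @param artifact_units unit ids whose light waveform should mismatch.
#' @param span_us snippet span around the trough, microseconds (default the
#'   opto-tagging correlation window -330 to 570; widen it when the positive
#'   peak of broad-spiking units must fall inside the snippet, e.g. for
#'   trough-to-peak measurement).
#' @return named list (by unit id) of lists with `spont`, `light`,
#'   `t_us`, `sample_period_us`.
#' @export
generate_waveforms <- function(units, seed = 1L, sample_period_us = 10,
                               noise_sd = 0.01, artifact_units = character(),
                               span_us = c(-330, 570)) {
  stopifnot(all(c("unit_id", "trough_to_peak_us") %in% names(units)))
  set.seed(as.integer(seed))
  out <- lapply(seq_len(nrow(units)), function(i) {
    ttp <- units$trough_to_peak_us[i]
    tmpl <- .waveform_template(ttp, sample_period_us, span_us = span_us)
    n <- length(tmpl$w)
    spont <- tmpl$w + stats::rnorm(n, 0, noise_sd)
    light <- if (units$unit_id[i] %in% artifact_units) {
      art <- .waveform_template(min(span_us[2], ttp * 1.8), sample_period_us,
                                trough_width_us = 220, span_us = span_us)
      -0.6 * art$w + stats::rnorm(n, 0, noise_sd)
    } else {
      tmpl$w + stats::rnorm(n, 0, noise_sd)
    }
    list(spont = spont, light = light, t_us = tmpl$t_us,
         sample_period_us = sample_period_us)
  })
  names(out) <- units$unit_id
  out
}

#' Generate light-pulse (opto-tagging) trials
#'
#' 75 trials of a 10 ms light pulse at 1.5 s spacing. Opto-tagged units fire
#' a brief high-rate burst starting at their light latency; untagged units
#' fire only spontaneously. Spike times are relative to pulse onset and span
#' `trial_span`.
#'
#' @param units data.frame with `unit_id`, `is_optotagged`,
#'   `light_latency_ms` and (optionally) `spont_rate` (Hz; default 2).
#' @param seed integer seed.
#' @param n_trials number of light trials (default 75).
#' @param pulse_dur light-pulse duration, s (default 0.010).
#' @param evoked_rate added rate during the evoked burst for tagged units, Hz.
#' @param evoked_dur duration of the evoked burst, s.
#' @param trial_span span of spike times kept around each pulse, s.
#' @return data.frame (`unit_id`, `trial_index`, `spike_time_s`).
#' @export
generate_opto_trials <- function(units, seed = 1L, n_trials = 75L,
                                 pulse_dur = 0.010, evoked_rate = 500,
                                 evoked_dur = 0.008,
                                 trial_span = c(-0.5, 0.5)) {
  stopifnot(all(c("unit_id", "is_optotagged", "light_latency_ms") %in%
                  names(units)))
  set.seed(as.integer(seed))
  spont <- if ("spont_rate" %in% names(units)) units$spont_rate else
    rep(2, nrow(units))
  res <- lapply(seq_len(nrow(units)), function(i) {
    n_sp <- stats::rpois(n_trials, spont[i] * diff(trial_span))
    tr <- rep.int(seq_len(n_trials) - 1L, n_sp)
    tt <- stats::runif(sum(n_sp), trial_span[1], trial_span[2])
    if (isTRUE(units$is_optotagged[i])) {
      lat <- units$light_latency_ms[i] / 1000
      n_ev <- stats::rpois(n_trials, evoked_rate * evoked_dur)
      tr <- c(tr, rep.int(seq_len(n_trials) - 1L, n_ev))
      tt <- c(tt, lat + stats::runif(sum(n_ev), 0, evoked_dur))
    }
    data.frame(unit_id = units$unit_id[i], trial_index = tr,
               spike_time_s = tt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$unit_id, out$trial_index, out$spike_time_s), ]
  rownames(out) <- NULL
  out
}

#' Generate a pre-filtered voltage snippet with embedded spikes
#'
#' Gaussian baseline noise with a known robust scale plus brief negative
#' deflections of amplitude `spike_amp` x MAD at Poisson event times (events
#' closer than 2 ms to a previous one are dropped so each corresponds to a
#' single threshold excursion).
#'
#' @param rate_hz embedded spike rate, Hz (0 = pure noise).
#' @param mad_scale target median absolute deviation of the baseline noise
#'   (normal-consistent, i.e. the robust SD).
#' @param spike_amp deflection amplitude in multiples of `mad_scale`.
#' @param seed integer seed.
#' @param duration_s trace duration (default 1 s).
#' @param fs sampling rate, Hz (default 24414).
#' @return list with `trace`, `fs`, `true_times` (s).
#' @export
generate_voltage_snippet <- function(rate_hz, mad_scale, spike_amp, seed = 1L,
                                     duration_s = 1, fs = 24414) {
  stopifnot(mad_scale > 0, rate_hz >= 0)
  set.seed(as.integer(seed))
  n <- round(duration_s * fs)
  v <- stats::rnorm(n, 0, mad_scale)
  times <- numeric(0)
  if (rate_hz > 0) {
    n_ev <- stats::rpois(1, rate_hz * duration_s)
    times <- sort(stats::runif(n_ev, 0.005, duration_s - 0.005))
    if (length(times) > 1)
      times <- times[c(TRUE, diff(times) > 0.002)]
    shape <- -spike_amp * mad_scale * c(0.3, 0.8, 1, 0.8, 0.3)
    idx <- round(times * fs) + 1L
    for (j in idx) {
      k <- j:(j + 4L)
      v[k] <- v[k] + shape
    }
  }
  list(trace = v, fs = fs, true_times = times)
}
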