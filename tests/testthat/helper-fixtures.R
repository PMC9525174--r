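# Shared fixtures and independent oracles, all built in code.

# dataset in which every trial carries the identical spike pattern
locked_dataset <- function(pattern = c(0.005, 0.155, 0.305, 0.955),
                           schedule = stimulus_schedule()) {
  spikes <- data.frame(
    unit_id = "locked",
    trial_index = rep(0:(schedule$n_trials - 1L), each = length(pattern)),
    spike_time_s = rep(pattern, schedule$n_trials))
  spike_dataset(spikes, schedule)
}

# brute-force Benjamini-Hochberg step-up: for each p, the minimum over all
# ranks j at or above its own of p_(j) * m / j, clipped at 1
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# measured FDI of one generated unit (headline: repetition 4, minus_prior)
measured_fdi <- function(dataset, unit_id, kind = "onset",
                         method = "minus_prior",
                         schedule = dataset$schedule) {
  p <- build_psth(dataset, unit_id, schedule)
  p <- zscore_and_normalize(p, baseline_stats(dataset, unit_id, schedule),
                            sd_floor = 1 / schedule$n_trials)
  det <- detect_all_windows(p, make_windows(schedule))
  rows <- det[det$kind == kind, ]
  rows <- rows[order(rows$index), ]
  fdi(rows[[paste0("mag_", method)]])
}

# z-scored + normalized PSTH of one unit
unit_psth <- function(dataset, unit_id, schedule = dataset$schedule) {
  zscore_and_normalize(build_psth(dataset, unit_id, schedule),
                       baseline_stats(dataset, unit_id, schedule),
                       sd_floor = 1 / schedule$n_trials)
}

# matrix of normalized PSTHs over the clustering span (first burst onset to
# one gap past the last burst)
norm_psth_matrix <- function(dataset, schedule = dataset$schedule) {
  ids <- unit_ids(dataset)
  rows <- lapply(ids, function(u) {
    p <- unit_psth(dataset, u, schedule)
    lo <- p$bin_edges[-length(p$bin_edges)]
    p$normalized[lo >= -1e-9 & lo < schedule$analysis_end - 1e-9]
  })
  M <- do.call(rbind, rows)
  rownames(M) <- ids
  M
}

# hand-built psth object with given raw rate and baseline stats
toy_psth <- function(rate, baseline_mean, baseline_sd, bin_s = 0.010,
                     start = -0.2) {
  p <- psth(rate, start + bin_s * (0:length(rate)))
  zscore_and_normalize(p, list(baseline_mean = baseline_mean,
                               baseline_sd = baseline_sd))
}
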