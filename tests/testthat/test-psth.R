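sch <- stimulus_schedule()

test_that("PSTH bins and averages spikes as spikes/bin/trial", {
  spikes <- data.frame(unit_id = "u", trial_index = 0:119,
                       spike_time_s = 0.005)
  ds <- spike_dataset(spikes, sch)
  p <- build_psth(ds, "u")
  lo <- p$bin_edges[-length(p$bin_edges)]
  expect_equal(p$rate[which(abs(lo) < 1e-9)], 1.0)
  expect_equal(sum(p$rate), 1.0)  # all other bins zero
  expect_error(build_psth(ds, "nope"), "unknown unit")
})

test_that("a unit with no spikes yields an all-zero PSTH", {
  spikes <- data.frame(unit_id = "u", trial_index = 0L, spike_time_s = 0.005)
  ds <- spike_dataset(spikes, sch,
                      units = data.frame(unit_id = c("u", "empty")))
  p <- build_psth(ds, "empty")
  expect_true(all(p$rate == 0))
})

test_that("Poisson firing produces the expected mean bin rate", {
  arch <- default_archetypes()
  arch$unresponsive$spont_rate <- 10
  gen <- generate_dataset(c(unresponsive = 1), sch, seed = 5,
                          archetypes = arch)
  p <- build_psth(gen$dataset, "u0001")
  n_bins <- length(p$rate)
  se <- sqrt(0.1 / (sch$n_trials * n_bins))
  expect_lt(abs(mean(p$rate) - 0.1), 3 * se)
})

test_that("PSTH conserves the spike count and ignores trial order", {
  gen <- generate_dataset(c(transient_depressing = 1), sch, seed = 9)
  ds <- gen$dataset
  p <- build_psth(ds, "u0001")
  in_span <- ds$spikes$spike_time_s >= sch$analysis_start &
    ds$spikes$spike_time_s < sch$analysis_end
  expect_equal(sum(p$rate) * sch$n_trials, sum(in_span))
  # permute trial labels
  perm <- sample(0:119)
  sp2 <- ds$spikes
  sp2$trial_index <- perm[sp2$trial_index + 1L]
  ds2 <- spike_dataset(sp2, sch)
  expect_equal(build_psth(ds2, "u0001")$rate, p$rate)
})

test_that("baseline statistics follow their definition", {
  # one spike in every 10 ms baseline bin, single trial: mean 1, SD 0
  sch1 <- stimulus_schedule(n_trials = 1)
  tt <- -4 + 0.005 + 0.010 * (0:399)
  ds <- spike_dataset(data.frame(unit_id = "u", trial_index = 0L,
                                 spike_time_s = tt), sch1)
  bs <- baseline_stats(ds, "u", sch1)
  expect_equal(bs$baseline_mean, 1.0)
  expect_equal(bs$baseline_sd, 0.0)
  # Poisson 10 Hz: mean near 0.1 spikes/bin/trial
  arch <- default_archetypes()
  arch$unresponsive$spont_rate <- 10
  gen <- generate_dataset(c(unresponsive = 1), sch, seed = 11,
                          archetypes = arch)
  bs2 <- baseline_stats(gen$dataset, "u0001")
  expect_lt(abs(bs2$baseline_mean - 0.1), 0.01)
  # silent baseline: mean 0, SD 0, and z-scoring must refuse without a floor
  ds0 <- spike_dataset(data.frame(unit_id = "u", trial_index = 0L,
                                  spike_time_s = 0.005), sch1)
  bs0 <- baseline_stats(ds0, "u", sch1)
  expect_equal(bs0$baseline_mean, 0)
  expect_equal(bs0$baseline_sd, 0)
  p0 <- build_psth(ds0, "u", sch1)
  expect_error(zscore_and_normalize(p0, bs0), "degenerate baseline")
  p0f <- zscore_and_normalize(p0, bs0, sd_floor = 1)
  expect_equal(max(p0f$zscored), 1)
})

test_that("z-scoring and normalization obey the absolute-maximum rule", {
  p <- psth(rep(0.5, 10), 0.01 * (0:10))
  z0 <- zscore_and_normalize(p, list(baseline_mean = 0.5, baseline_sd = 0.1))
  expect_true(all(z0$zscored == 0))
  expect_true(all(z0$normalized == 0))
  # peak 8 -> normalized peak 1
  p2 <- psth(c(rep(0.1, 9), 0.9), 0.01 * (0:10))
  z2 <- zscore_and_normalize(p2, list(baseline_mean = 0.1, baseline_sd = 0.1))
  expect_equal(max(z2$zscored), 8)
  expect_equal(max(z2$normalized), 1)
  # trough -4, peak +2 -> normalized trough -1 (absolute-max rule)
  p3 <- psth(c(0.0, 0.6, rep(0.4, 8)), 0.01 * (0:10))
  z3 <- zscore_and_normalize(p3, list(baseline_mean = 0.4, baseline_sd = 0.1))
  expect_equal(min(z3$zscored), -4)
  expect_equal(max(z3$zscored), 2)
  expect_equal(min(z3$normalized), -1)
  # renormalizing the normalized view is idempotent
  expect_equal(z3$normalized / max(abs(z3$normalized)), z3$normalized)
})

test_that("onset latency finds a rate step through the smoothed PSTH", {
  set.seed(31)
  n_ev <- 300
  sim_rel <- function(step_at) {
    base <- stats::runif(stats::rpois(1, 5 * 0.1 * n_ev), -0.1, 0)
    ev <- stats::runif(stats::rpois(1, 400 * (0.1 - step_at) * n_ev),
                       step_at, 0.1)
    c(base, ev)
  }
  lat <- latency_from_rel_times(sim_rel(0.012), n_ev)
  expect_lte(abs(lat - 12), 2)
  expect_lte(latency_from_rel_times(sim_rel(0), n_ev), 2)
  # flat firing: no latency
  flat <- stats::runif(500, -0.1, 0.1)
  expect_true(is.na(latency_from_rel_times(flat, n_ev)))
  # no baseline spikes at all: degenerate baseline
  expect_error(latency_from_rel_times(c(0.01, 0.02), 10), "degenerate")
})
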