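sch <- stimulus_schedule()

test_that("generation is deterministic in the seed and rejects empty mixes", {
  g1 <- generate_dataset(c(transient_depressing = 2), sch, seed = 1)
  g2 <- generate_dataset(c(transient_depressing = 2), sch, seed = 1)
  expect_identical(g1$dataset$spikes, g2$dataset$spikes)
  expect_identical(g1$ground_truth, g2$ground_truth)
  g3 <- generate_dataset(c(transient_depressing = 2), sch, seed = 2)
  expect_false(identical(g1$dataset$spikes, g3$dataset$spikes))
  expect_error(generate_dataset(c(transient_depressing = 0), sch, seed = 1),
               "no units")
  expect_error(generate_dataset(integer(0), sch, seed = 1), "no units")
})

test_that("unresponsive units fire at their spontaneous rate in every window", {
  gen <- generate_dataset(c(unresponsive = 5), sch, seed = 7)
  spont <- default_archetypes()$unresponsive$spont_rate
  win <- make_windows(sch)
  win <- win[win$part == "full", ]
  for (u in unit_ids(gen$dataset)) {
    p <- build_psth(gen$dataset, u, sch)
    for (i in seq_len(nrow(win))) {
      idx <- which(p$bin_edges[-length(p$bin_edges)] >= win$start[i] - 1e-9 &
                     p$bin_edges[-length(p$bin_edges)] < win$end[i] - 1e-9)
      n_obs <- sum(p$rate[idx]) * sch$n_trials
      n_exp <- spont * (win$end[i] - win$start[i]) * sch$n_trials
      expect_lt(abs(n_obs - n_exp), 3 * sqrt(n_exp))
    }
  }
})

test_that("planted depression is recovered: FDI near its analytic value", {
  arch <- default_archetypes()
  arch$transient_depressing$per_rep_factor_onset <- c(1, 0.8, 0.6, 0.5)
  arch$transient_depressing$onset_amp <- 500  # response dominates noise
  gen <- generate_dataset(c(transient_depressing = 1), sch, seed = 2,
                          archetypes = arch)
  expect_equal(gen$ground_truth$expected_fdi_onset, -0.5)
  expect_lt(abs(measured_fdi(gen$dataset, "u0001") - (-0.5)), 0.1)
})

test_that("generator is calibrated: mean measured FDI matches the planted gains", {
  vals <- vapply(1:100, function(s) {
    gen <- generate_dataset(c(transient_depressing = 1), sch, seed = s)
    measured_fdi(gen$dataset, "u0001")
  }, numeric(1))
  analytic <- with(default_archetypes()$transient_depressing,
                   (per_rep_factor_onset[4] - 1) / max(per_rep_factor_onset))
  expect_lt(abs(mean(vals) - analytic), 0.05)
})

test_that("z-scored baselines of unresponsive units are honest (mean |z| small)", {
  gen <- generate_dataset(c(unresponsive = 10), sch, seed = 21)
  zmeans <- vapply(unit_ids(gen$dataset), function(u) {
    p <- unit_psth(gen$dataset, u)
    lo <- p$bin_edges[-length(p$bin_edges)]
    mean(p$zscored[lo < 0])
  }, numeric(1))
  expect_lt(mean(abs(zmeans)), 0.2)
})

test_that("waveform templates carry the requested trough-to-peak delay", {
  units <- data.frame(unit_id = c("a", "b"),
                      trough_to_peak_us = c(400, 550))
  wf <- generate_waveforms(units, seed = 3, noise_sd = 0)
  expect_equal(trough_to_peak(wf[["a"]]$spont, 10), 400)
  expect_equal(trough_to_peak(wf[["b"]]$spont, 10), 550)
  # snippet span follows the opto-tagging correlation window
  expect_equal(range(wf[["a"]]$t_us), c(-330, 570))
})

test_that("light and spontaneous waveforms match for tagged units, not for artifacts", {
  units <- data.frame(unit_id = c("tag", "art"),
                      trough_to_peak_us = c(350, 350))
  wf <- generate_waveforms(units, seed = 5, artifact_units = "art")
  expect_gte(cor(wf[["tag"]]$spont, wf[["tag"]]$light), 0.95)
  expect_lt(cor(wf[["art"]]$spont, wf[["art"]]$light), 0.95)
})

test_that("opto trials: 75 trials, tagged latency within bound, untagged stay at baseline", {
  units <- data.frame(unit_id = c("tag", "un"),
                      is_optotagged = c(TRUE, FALSE),
                      light_latency_ms = c(3, 3), spont_rate = c(8, 8))
  lt <- generate_opto_trials(units, seed = 4)
  expect_equal(sort(unique(lt$trial_index)), 0:74)
  tagged <- lt[lt$unit_id == "tag", ]
  lat <- latency_from_rel_times(tagged$spike_time_s, 75)
  expect_lte(lat, 5)
  # untagged units: light-evoked firing not significantly elevated (alpha
  # 0.01) in at least 90% of seeds
  sig <- vapply(1:50, function(s) {
    l <- generate_opto_trials(units[2, , drop = FALSE], seed = 100 + s)
    optotag(l, waveforms = NULL)$p_elevation < 0.01
  }, logical(1))
  expect_gte(mean(!sig), 0.9)
})

test_that("voltage snippets embed detectable spikes with known MAD scaling", {
  vs <- generate_voltage_snippet(20, 1, 8, seed = 4)
  ev <- detect_mua_crossings(vs$trace, vs$fs)
  expect_equal(length(ev), length(vs$true_times))
  expect_true(all(abs(ev - vs$true_times) < 0.001))
  weak <- generate_voltage_snippet(20, 1, 2, seed = 4)
  expect_length(detect_mua_crossings(weak$trace, weak$fs), 0)
  silent <- generate_voltage_snippet(0, 1, 8, seed = 4)
  expect_length(silent$true_times, 0)
  expect_length(detect_mua_crossings(silent$trace, silent$fs), 0)
})
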