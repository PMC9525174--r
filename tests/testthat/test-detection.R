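sch <- stimulus_schedule()

test_that("windows tile the stimulus with correct arithmetic", {
  w <- make_windows(sch)
  expect_equal(nrow(w), 8)
  on1 <- w[w$kind == "onset" & w$index == 1, ]
  expect_equal(c(on1$start, on1$end), c(0, 0.15))
  expect_equal(c(on1$prior_start, on1$prior_end), c(-0.05, 0))
  off4 <- w[w$kind == "offset" & w$index == 4, ]
  expect_equal(c(off4$start, off4$end), c(1.05, 1.20))
  # early/late sub-windows
  we <- make_windows(sch, early_late = TRUE)
  expect_equal(nrow(we), 24)
  e2 <- we[we$kind == "onset" & we$index == 2 & we$part == "early", ]
  expect_equal(c(e2$start, e2$end), c(0.30, 0.35))
  l3 <- we[we$kind == "offset" & we$index == 3 & we$part == "late", ]
  expect_equal(c(l3$start, l3$end), c(0.85, 0.90))
  # tiling: every PSTH bin in [0, analysis_end) is in exactly one full window
  full <- w
  lo <- seq(0, sch$analysis_end - 0.01, by = 0.01) + 1e-9
  hits <- vapply(lo, function(t) sum(t >= full$start & t < full$end),
                 numeric(1))
  expect_true(all(hits == 1))
})

test_that("each of the three thresholds gates detection", {
  base <- rep(0.10, 20)
  mk <- function(peak, prior = 0.0, bm = 0.10, bsd = 0.05) {
    # 20 baseline bins, a 5-bin prior window, then a 15-bin response window
    rate <- c(base, rep(prior, 5), rep(bm, 5), peak, rep(bm, 9))
    p <- toy_psth(rate, bm, bsd)
    w <- data.frame(kind = "onset", index = 1, part = "full",
                    start = -0.2 + 0.25, end = -0.2 + 0.40,
                    prior_start = -0.2 + 0.20, prior_end = -0.2 + 0.25)
    detect_response(p, w)
  }
  # all gates pass: z = (0.5-0.1)/0.05 = 8, abs excess 0.4, prior 0
  expect_true(mk(0.5, prior = 0)$detected)
  # z gate alone fails: z = 2.9
  r <- mk(0.10 + 2.9 * 0.05, prior = 0)
  expect_true(r$gate_abs && r$gate_prior && !r$gate_z)
  expect_false(r$detected)
  # absolute gate alone fails: tiny SD makes z huge but excess 0.02 < 0.025
  r2 <- mk(0.12, prior = 0, bsd = 0.001)
  expect_true(r2$gate_z && r2$gate_prior && !r2$gate_abs)
  expect_false(r2$detected)
  # prior gate alone fails: lingering firing, max 0.5 < 3 x 0.2
  r3 <- mk(0.5, prior = 0.2)
  expect_true(r3$gate_abs && r3$gate_z && !r3$gate_prior)
  expect_false(r3$detected)
  # zero prior firing: the prior gate is vacuous
  expect_true(mk(0.5, prior = 0)$gate_prior)
})

test_that("magnitudes follow their subtraction methods", {
  flat <- toy_psth(rep(0.1, 40), 0.1, 0.02)
  w <- data.frame(kind = "onset", index = 1, part = "full",
                  start = -0.2 + 0.25, end = -0.2 + 0.40,
                  prior_start = -0.2 + 0.20, prior_end = -0.2 + 0.25)
  expect_equal(measure_magnitude(flat, w, "minus_prior"), 0)
  expect_equal(measure_magnitude(flat, w, "minus_baseline"), 0)
  expect_equal(measure_magnitude(flat, w, "auc"), 0)
  # max 0.5 above prior 0.1
  rate <- c(rep(0.1, 25), rep(0.1, 5), 0.5, rep(0.1, 9))
  p <- toy_psth(rate, 0.1, 0.02)
  expect_equal(measure_magnitude(p, w, "minus_prior"), 0.4)
  # box response 0.2 above prior over all 15 bins: auc = 3.0
  rate2 <- c(rep(0.1, 25), rep(0.3, 15))
  p2 <- toy_psth(rate2, 0.1, 0.02)
  expect_equal(measure_magnitude(p2, w, "auc"), 15 * 0.2)
  expect_error(measure_magnitude(p2, w, "nope"))
  # minus_prior and minus_baseline agree exactly when prior = baseline
  expect_equal(measure_magnitude(p2, w, "minus_prior"),
               measure_magnitude(p2, w, "minus_baseline"))
})

test_that("detection sensitivity is monotone in response amplitude", {
  amps <- seq(0, 0.2, by = 0.01)
  det <- vapply(amps, function(a) {
    rate <- c(rep(0.02, 25), 0.02 + a, rep(0.02, 14))
    p <- toy_psth(rate, 0.02, 0.01)
    w <- data.frame(kind = "onset", index = 1, part = "full",
                    start = -0.2 + 0.25, end = -0.2 + 0.40,
                    prior_start = -0.2 + 0.20, prior_end = -0.2 + 0.25)
    detect_response(p, w)$detected
  }, logical(1))
  expect_true(all(diff(det) >= 0))   # never un-detects as amplitude grows
  expect_false(det[1]); expect_true(det[length(det)])
})

test_that("responsiveness labels follow the per-window detections", {
  mk <- function(det_on, det_off) {
    data.frame(kind = rep(c("onset", "offset"), each = 4),
               index = rep(1:4, 2), part = "full",
               detected = c(det_on, det_off))
  }
  expect_equal(classify_responsiveness(mk(c(TRUE, rep(FALSE, 3)),
                                          rep(FALSE, 4))), "onset_only")
  expect_equal(classify_responsiveness(mk(c(TRUE, rep(FALSE, 3)),
                                          c(FALSE, FALSE, TRUE, FALSE))),
               "both")
  expect_equal(classify_responsiveness(mk(rep(FALSE, 4),
                                          c(rep(FALSE, 3), TRUE))),
               "offset_only")
  expect_equal(classify_responsiveness(mk(rep(FALSE, 4), rep(FALSE, 4))),
               "neither")
  # planted responses are detected in at least one matching window
  gen <- generate_dataset(c(transient_depressing = 1, offset_only = 1,
                            onset_and_offset = 1), sch, seed = 41)
  win <- make_windows(sch)
  for (i in 1:3) {
    u <- gen$ground_truth$unit_id[i]
    det <- detect_all_windows(unit_psth(gen$dataset, u), win)
    arch <- gen$ground_truth$archetype[i]
    if (arch != "offset_only")
      expect_true(any(det$detected[det$kind == "onset"]))
    if (arch != "transient_depressing")
      expect_true(any(det$detected[det$kind == "offset"]))
  }
})
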