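# PPG chain: quality assessment, reconstruction, peak detection, HRV.

test_that("SQA features behave as defined on canonical inputs", {
  # constant signal: zero spread, degenerate cycles
  f <- compute_sqa_features(rep(1, 750), 25)
  expect_equal(unname(f["iqr"]), 0)
  expect_equal(unname(f["sd_psd"]), 0)
  expect_true(isTRUE(attr(f, "degenerate")))
  expect_identical(classify_quality(f), "noisy")
  # noiseless pulse train: near-identical cycles
  s <- simulate_ppg_segment(72, 0, 30, 25, noise = ppg_noise_spec(rate = 0),
                            seed = 3)
  fc <- compute_sqa_features(s$samples, 25)
  expect_gte(fc["mean_template_corr"], 0.99)
  expect_identical(classify_quality(fc), "clean")
  # burst noise inflates spread features
  sn <- s$samples
  idx <- 200:420
  sn[idx] <- sn[idx] + 6 * sin(2 * pi * 0.3 * idx / 25) + rnorm(length(idx), 0, 1.5)
  fn <- compute_sqa_features(sn, 25)
  expect_gt(fn["iqr"], fc["iqr"])
  expect_gt(fn["cycle_energy_range"], fc["cycle_energy_range"])
  # values exactly at the thresholds count as clean (strict crossing)
  thr <- sqa_default_thresholds()
  at <- thr
  attr(at, "degenerate") <- FALSE
  expect_identical(classify_quality(at, thr), "clean")
})

test_that("reconstruction repairs only short interior noisy runs", {
  s <- simulate_ppg_segment(75, 40, 720, 25, noise = ppg_noise_spec(rate = 0),
                            seed = 12)
  sqa <- segment_sqa(s$samples, 25)
  expect_true(all(sqa$quality == "clean"))
  # all-clean mask: identity
  fix <- reconstruct_segment(s$samples, 25, sqa$quality)
  expect_identical(fix$samples, s$samples)
  inject <- function(x, from_s, dur_s) {
    idx <- round(from_s * 25):round((from_s + dur_s) * 25)
    x[idx] <- x[idx] + 6 * sin(2 * pi * 0.3 * idx / 25) +
      rnorm(length(idx), 0, 1.5)
    x
  }
  # one 10-s interior burst: repaired, relabelled clean, beat count kept
  set.seed(13)
  x10 <- inject(s$samples, 200, 10)
  sq10 <- segment_sqa(x10, 25)
  expect_true(any(sq10$quality == "noisy"))
  fix10 <- reconstruct_segment(x10, 25, sq10$quality)
  expect_true(all(fix10$quality == "clean"))
  expect_true(any(fix10$reconstructed))
  det <- detect_systolic_peaks(fix10$samples, 25, fix10$quality)
  truth_n <- sum(s$beats >= 198 & s$beats <= 212)
  got_n <- sum(det$beat_times >= 198 & det$beat_times <= 212)
  expect_lte(abs(got_n - truth_n), 1)
  # one 20-s burst: >= 15 s rule leaves the run noisy
  set.seed(14)
  x20 <- inject(s$samples, 300, 20)
  sq20 <- segment_sqa(x20, 25)
  fix20 <- reconstruct_segment(x20, 25, sq20$quality)
  expect_true(any(fix20$quality == "noisy"))
  expect_false(any(fix20$reconstructed))
  # entirely noisy segment: returned unchanged
  allq <- rep("noisy", length(sq10$quality))
  fixall <- reconstruct_segment(x10, 25, allq)
  expect_identical(fixall$samples, x10)
  expect_true(all(fixall$quality == "noisy"))
})

test_that("peak detection recovers beats and screens IBIs", {
  s <- simulate_ppg_segment(60, 0, 120, 25, noise = ppg_noise_spec(rate = 0),
                            seed = 2)
  det <- detect_systolic_peaks(s$samples, 25)
  expect_true(all(abs(det$ibis_ms - 1000) <= 10))
  # flat signal: empty series
  flat <- detect_systolic_peaks(rep(0.5, 3000), 25)
  expect_length(flat$beat_times, 0)
  # no clean windows: empty series
  none <- detect_systolic_peaks(s$samples, 25, quality = rep("noisy", 4))
  expect_length(none$beat_times, 0)
  # IBI validity rules: range and 30% successive-change screening
  # (2500 ms out of range; 600 ms is a 40% drop from the last valid 1000 ms)
  ib <- ibi_series(c(0, 1, 2, 4.5, 5.1, 5.9))
  expect_equal(ib$ibis_ms, c(1000, 1000, 2500, 600, 800))
  expect_equal(ib$valid, c(TRUE, TRUE, FALSE, FALSE, TRUE))
})

test_that("HRV features match hand arithmetic and the identity set", {
  # constant 800 ms IBIs
  ib <- ibi_series(seq(0, by = 0.8, length.out = 16))
  h <- compute_hrv_features(ib, 12.8)
  expect_equal(unname(h["mean_nn"]), 800)
  expect_equal(unname(h["hr"]), 75)
  expect_equal(unname(h[c("sdnn", "rmssd", "cvsd")]), c(0, 0, 0))
  # alternating 800/1000 ms (12 intervals)
  bt <- cumsum(c(0, rep(c(0.8, 1), 6)))
  h2 <- compute_hrv_features(ibi_series(bt), sum(rep(c(0.8, 1), 6)))
  expect_equal(unname(h2["rmssd"]), 200)
  expect_equal(unname(h2["sdnn"]), 100)
  expect_equal(unname(h2["cvsd"]), 200 / 900, tolerance = 1e-12)
  # too few IBIs: missing-marked with a reason
  h3 <- compute_hrv_features(ibi_series(c(0, 0.8, 1.6)), 2.4)
  expect_true(all(is.na(h3[c("mean_nn", "sdnn")])))
  expect_match(attr(h3, "reason"), "valid IBIs")
})

test_that("spectral band powers recover known sinusoid variance", {
  # NN series with pure LF and HF oscillations at bin-centred frequencies
  fs <- 4
  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  a_lf <- 30; a_hf <- 18
  y <- 900 + a_lf * sin(2 * pi * 0.10 * t) + a_hf * sin(2 * pi * 0.25 * t)
  spec <- welch_psd(y - mean(y), fs, nseg = 480)
  lf <- band_power(spec, 0.04, 0.15)
  hf <- band_power(spec, 0.15, 0.4)
  expect_lt(abs(lf - a_lf^2 / 2) / (a_lf^2 / 2), 0.02)
  expect_lt(abs(hf - a_hf^2 / 2) / (a_hf^2 / 2), 0.02)
  # normalized powers always sum to one when defined
  s <- simulate_ppg_segment(70, 45, 720, 25, noise = ppg_noise_spec(rate = 0),
                            seed = 9)
  h <- process_ppg_segment(s$samples, 25)$hrv
  expect_equal(unname(h["lfn"] + h["hfn"]), 1, tolerance = 1e-9)
})
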