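# Synthetic PPG segments with known beats and noise masks.
#
# Each beat contributes a systolic Gaussian peak plus a smaller, delayed
# dicrotic component on a slow respiratory-style baseline; this is the
# simplest waveform with an unambiguous systolic maximum, which is what the
# peak-detection stand-in needs to be testable. Motion-noise bursts add
# large-amplitude baseline wander and broadband noise over recorded sample
# ranges.

#' Simulate one PPG segment
#'
#' @param mean_hr mean heart rate, beats/min (30-220)
#' @param hrv_sd beat-to-beat IBI jitter SD, ms
#' @param duration_s segment duration, s
#' @param fs sampling rate, samples/s
#' @param noise a [ppg_noise_spec()]
#' @param seed optional integer seed for an isolated, reproducible draw
#' @return list with `samples` (numeric), `fs`, `beats` (true systolic peak
#'   times, s, strictly increasing), `ibis_ms` (true inter-beat intervals),
#'   `noise_mask` (logical per sample)
#' @export
simulate_ppg_segment <- function(mean_hr, hrv_sd, duration_s, fs,
                                 noise = ppg_noise_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (duration_s <= 0 || fs <= 0) stop("duration and fs must be positive")
  if (mean_hr < 30 || mean_hr > 220) stop("mean_hr must be in [30, 220] bpm")
  mean_ibi <- 60 / mean_hr
  if (duration_s / mean_ibi < 2) stop("segment too short for two beats")

  n_max <- ceiling(duration_s / mean_ibi * 1.5) + 8L
  ibis <- rnorm(n_max, mean_ibi, hrv_sd / 1000)
  ibis <- pmax(ibis, 0.3)
  beats <- runif(1, 0.1, 0.1 + mean_ibi) + cumsum(c(0, ibis))
  beats <- beats[beats < duration_s - 0.05]

  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  base_phase <- runif(1, 0, 2 * pi)
  wave <- 0.15 * sin(2 * pi * 0.08 * t + base_phase)

  d <- diff(c(beats, beats[length(beats)] + mean_ibi))
  amp <- 1 + rnorm(length(beats), 0, 0.05)
  wave <- cpp_add_pulses(wave, fs, beats, amp, 0.09 * sqrt(d))
  wave <- cpp_add_pulses(wave, fs, beats + 0.35 * d, 0.35 * amp, 0.12 * sqrt(d))

  mask <- rep(FALSE, n)
  n_bursts <- rpois(1, noise$rate)
  if (n_bursts > 0) {
    for (b in seq_len(n_bursts)) {
      short <- runif(1) < noise$p_short
      bd <- if (short) runif(1, noise$dur_short[1], noise$dur_short[2])
            else runif(1, noise$dur_long[1], noise$dur_long[2])
      bd <- min(bd, duration_s)
      b0 <- runif(1, 0, duration_s - bd)
      idx <- which(t >= b0 & t < b0 + bd)
      f_w <- runif(1, 0.1, 0.5)
      ph <- runif(1, 0, 2 * pi)
      wave[idx] <- wave[idx] +
        noise$amp_wander * sin(2 * pi * f_w * t[idx] + ph) +
        rnorm(length(idx), 0, noise$amp_white)
      mask[idx] <- TRUE
    }
  }
  list(samples = wave, fs = fs, beats = beats,
       ibis_ms = 1000 * diff(beats), noise_mask = mask)
}
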