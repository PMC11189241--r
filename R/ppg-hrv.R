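# HR/HRV features from an IBI series (one value per feature per segment).
#
# Conventions: population (ddof 0) SD everywhere; RMSSD over successive
# valid IBI pairs only; spectral features from a 4 Hz linearly interpolated
# NN series, linearly detrended, Welch PSD (120-s Hann segments, 50%
# overlap), band integration LF [0.04, 0.15) Hz / HF [0.15, 0.4) Hz;
# SDANN1/SDANN5 over complete 1-min / 5-min bins (a 12-minute segment has
# only 2 complete 5-min bins, so SDANN5 carries a low-confidence flag).

HRV_FEATURES <- c("mean_nn", "hr", "sdnn", "rmssd", "cvsd", "cvnn",
                  "lf", "hf", "lfn", "hfn", "sdann1", "sdann5",
                  "n_valid_ibis")
HRV_MIN_IBIS <- 10
HRV_SPECTRAL_MIN_SPAN_S <- 120
HRV_INTERP_FS <- 4
HRV_WELCH_SEG_S <- 120

#' Compute HR/HRV features from an IBI series
#'
#' @param ibis an [ibi_series()]
#' @param segment_duration_s recording duration, s (for SDANN binning)
#' @return named numeric vector of the 13 features; all `NA` (with a
#'   `reason` attribute) when fewer than 10 valid IBIs are available;
#'   spectral fields `NA` when the valid span is under 2 minutes
#' @export
compute_hrv_features <- function(ibis, segment_duration_s = 720) {
  out <- setNames(rep(NA_real_, length(HRV_FEATURES)), HRV_FEATURES)
  v <- which(ibis$valid)
  out["n_valid_ibis"] <- length(v)
  if (length(v) < HRV_MIN_IBIS) {
    attr(out, "reason") <- "fewer than 10 valid IBIs"
    return(out)
  }
  nn <- ibis$ibis_ms[v]
  out["mean_nn"] <- mean(nn)
  out["hr"] <- 60000 / out["mean_nn"]
  out["sdnn"] <- pop_sd(nn)
  succ <- v[which(diff(v) == 1L)]  # valid pairs adjacent in the beat sequence
  if (length(succ) >= 1) {
    d <- ibis$ibis_ms[succ + 1L] - ibis$ibis_ms[succ]
    out["rmssd"] <- sqrt(mean(d^2))
  }
  out["cvsd"] <- out["rmssd"] / out["mean_nn"]
  out["cvnn"] <- out["sdnn"] / out["mean_nn"]

  # NN value timestamped at the closing beat of each valid interval
  t_nn <- ibis$beat_times[v + 1L]
  for (bin_s in c(60, 300)) {
    nb <- floor(segment_duration_s / bin_s)
    if (nb >= 2) {
      bin <- floor(t_nn / bin_s) + 1L
      keep <- bin <= nb
      if (length(unique(bin[keep])) >= 2) {
        means <- tapply(nn[keep], bin[keep], mean)
        out[if (bin_s == 60) "sdann1" else "sdann5"] <- pop_sd(means)
      }
    }
  }

  span <- diff(range(t_nn))
  if (span >= HRV_SPECTRAL_MIN_SPAN_S && length(v) >= 20) {
    tt <- seq(t_nn[1], t_nn[length(t_nn)], by = 1 / HRV_INTERP_FS)
    y <- approx(t_nn, nn, xout = tt)$y
    y <- stats::residuals(stats::lm.fit(cbind(1, tt), y))  # linear detrend
    spec <- welch_psd(y, HRV_INTERP_FS,
                      nseg = min(length(y), HRV_WELCH_SEG_S * HRV_INTERP_FS))
    out["lf"] <- band_power(spec, 0.04, 0.15)
    out["hf"] <- band_power(spec, 0.15, 0.4)
    tot <- out["lf"] + out["hf"]
    if (tot > 0) {
      out["lfn"] <- out["lf"] / tot
      out["hfn"] <- out["hf"] / tot
    }
  }
  out
}

#' Run the full PPG chain on one segment
#'
#' Quality assessment, short-gap reconstruction, systolic peak detection
#' and HRV feature extraction.
#'
#' @param samples PPG sample vector
#' @param fs sampling rate, samples/s
#' @param window_s SQA window, s
#' @param thresholds SQA cutoffs
#' @param reconstruct repair sub-15-s noisy runs before peak detection?
#' @return list: `hrv` (named features), `ibis` ([ibi_series()]), `quality`,
#'   `reconstructed`, `sqa` (per-window feature matrix)
#' @export
process_ppg_segment <- function(samples, fs, window_s = SQA_WINDOW_S,
                                thresholds = sqa_default_thresholds(),
                                reconstruct = TRUE) {
  sqa <- segment_sqa(samples, fs, window_s, thresholds)
  quality <- sqa$quality
  recon <- rep(FALSE, length(quality))
  if (reconstruct) {
    fix <- reconstruct_segment(samples, fs, quality, window_s)
    samples <- fix$samples
    quality <- fix$quality
    recon <- fix$reconstructed
  }
  # the SQA's raw peaks can be reused unless reconstruction altered samples
  ib <- detect_systolic_peaks(samples, fs, quality, window_s,
                              peaks = if (!any(recon)) sqa$peaks)
  hrv <- compute_hrv_features(ib, length(samples) / fs)
  list(hrv = hrv, ibis = ib, quality = quality, reconstructed = recon,
       sqa = sqa$features)
}

#' Extract the per-segment HRV stream for a whole cohort
#'
#' Realizes each observed PPG segment, runs the processing chain and emits
#' one row of HRV features per segment (streaming; waveforms are discarded
#' as soon as they are processed).
#'
#' @param cohort a `lonesense_cohort`
#' @param reconstruct passed to [process_ppg_segment()]
#' @return data.table: `participant_id`, `start_time`, `end_time`, one
#'   column per HRV feature
#' @export
extract_hrv_stream <- function(cohort, reconstruct = TRUE) {
  segs <- cohort$ppg_segments[observed == TRUE]
  res <- matrix(NA_real_, nrow(segs), length(HRV_FEATURES),
                dimnames = list(NULL, HRV_FEATURES))
  for (i in seq_len(nrow(segs))) {
    s <- simulate_ppg_segment(segs$mean_hr[i], segs$hrv_sd_ms[i],
                              segs$duration_s[i], segs$fs[i],
                              noise = ppg_noise_spec(rate = cohort$config$noise_burst_rate),
                              seed = segs$seg_seed[i])
    res[i, ] <- process_ppg_segment(s$samples, s$fs,
                                    reconstruct = reconstruct)$hrv
  }
  out <- data.table(participant_id = segs$participant_id,
                    start_time = segs$start_time,
                    end_time = segs$start_time + segs$duration_s)
  cbind(out, as.data.table(res))
}
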