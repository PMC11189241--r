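# Systolic peak detection and IBI construction.
#
# Deterministic stand-in for a learned peak detector: band-pass 0.5-8 Hz,
# local maxima above an adaptive threshold (a fraction of the block-wise
# 75th-percentile amplitude), a 300 ms refractory rule, and parabolic
# sub-sample refinement (without which 25 Hz sampling would floor RMSSD
# accuracy at ~40 ms).

PPG_BAND_HZ <- c(0.5, 8)
PPG_REFRACTORY_S <- 0.3
PPG_THRESH_FRAC <- 0.6
IBI_VALID_MS <- c(300, 2000)
IBI_MAX_REL_CHANGE <- 0.3

.butter_cache <- new.env(parent = emptyenv())

bandpass_ppg <- function(x, fs) {
  key <- as.character(fs)
  bf <- .butter_cache[[key]]
  if (is.null(bf)) {
    hi <- min(PPG_BAND_HZ[2], 0.45 * fs)
    bf <- signal::butter(2, c(PPG_BAND_HZ[1], hi) / (fs / 2), type = "pass")
    .butter_cache[[key]] <- bf
  }
  # centering removes the DC step transient (a constant signal maps to 0)
  cpp_filtfilt(x - mean(x), bf$b, bf$a)
}

# raw peak detection on a (sub)signal; returns refined peak times in
# seconds. Adaptive threshold: fraction of the block-wise 75th percentile
# of local-maximum amplitudes, so the systolic peaks set the scale and the
# smaller dicrotic maxima fall below it.
detect_peaks_raw <- function(x, fs, bp = NULL) {
  if (length(x) < fs) return(numeric(0))
  if (is.null(bp)) bp <- bandpass_ppg(x, fs)
  tt <- cpp_detect_peaks(bp, fs, block_s = 10, frac = PPG_THRESH_FRAC,
                         refractory_s = PPG_REFRACTORY_S)
  if (is.unsorted(tt)) tt <- sort(tt)
  tt
}

#' Build an IBI series from beat times
#'
#' Applies physiological screening: an IBI is valid if it lies in
#' [300, 2000] ms and differs from the previous valid IBI by at most 30%.
#'
#' @param beat_times strictly increasing beat times, seconds
#' @return list of class `ibi_series`: `beat_times`, `ibis_ms`
#'   (`1000 * diff(beat_times)`), `valid`
#' @export
ibi_series <- function(beat_times) {
  stopifnot(!is.unsorted(beat_times, strictly = TRUE))
  ibis <- 1000 * diff(beat_times)
  valid <- logical(length(ibis))
  prev <- NA_real_
  for (i in seq_along(ibis)) {
    ok <- ibis[i] >= IBI_VALID_MS[1] && ibis[i] <= IBI_VALID_MS[2] &&
      (is.na(prev) || abs(ibis[i] - prev) <= IBI_MAX_REL_CHANGE * prev)
    valid[i] <- ok
    if (ok) prev <- ibis[i]
  }
  structure(list(beat_times = beat_times, ibis_ms = ibis, valid = valid),
            class = "ibi_series")
}

#' Detect systolic peaks in a quality-assessed PPG segment
#'
#' Peaks are detected on the band-passed signal and kept only when they fall
#' in clean (or reconstructed) analysis windows; the resulting IBI series
#' carries validity flags, with window-exclusion gaps surfacing as invalid
#' over-long intervals.
#'
#' @param samples PPG sample vector
#' @param fs sampling rate, samples/s
#' @param quality per-window labels, `"clean"`/`"noisy"` (reconstructed
#'   windows are labelled clean); `NULL` treats the whole segment as clean
#' @param window_s analysis-window length, s
#' @param peaks optional precomputed raw peak times (skips re-detection)
#' @return an [ibi_series()] (empty if no clean windows)
#' @export
detect_systolic_peaks <- function(samples, fs, quality = NULL, window_s = 30,
                                  peaks = NULL) {
  if (!is.null(quality) && !any(quality == "clean"))
    return(structure(list(beat_times = numeric(0), ibis_ms = numeric(0),
                          valid = logical(0)), class = "ibi_series"))
  pk <- peaks %||% detect_peaks_raw(samples, fs)
  if (!is.null(quality)) {
    win <- pmin(floor(pk / window_s) + 1L, length(quality))
    pk <- pk[quality[win] == "clean"]
  }
  if (length(pk) < 2)
    return(structure(list(beat_times = pk, ibis_ms = numeric(0),
                          valid = logical(0)), class = "ibi_series"))
  ibi_series(pk)
}
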