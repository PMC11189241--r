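# Short-gap reconstruction of noisy PPG runs.
#
# Deterministic stand-in for a learned reconstructor, preserving the
# pipeline contract: sample-level noisy runs shorter than 15 s that are
# bounded by clean signal are replaced by a template pulse train tiled at
# the local IBI (with the local beat-to-beat jitter pattern mirrored so the
# repaired stretch keeps the surrounding IBI variability), amplitude-matched
# and crossfaded at the boundaries; runs of 15 s or more, or runs touching
# a segment edge, are left noisy and excluded downstream.

PPG_RECON_MAX_S <- 15
PPG_CROSSFADE_S <- 0.25

# locate the contiguous noisy sample run inside a run of flagged windows:
# samples whose deviation from the clean-signal median exceeds a robust
# bound, dilated by half a second
locate_noisy_run <- function(samples, fs, from, to, clean_idx) {
  ref <- samples[clean_idx]
  med <- median(ref)
  thr <- med + c(-1, 1) * max(3.5 * diff(quantile(ref, c(0.25, 0.75))), 1e-6)
  span <- from:to
  bad <- samples[span] < thr[1] | samples[span] > thr[2]
  if (!any(bad)) return(NULL)
  pad <- round(0.5 * fs)
  c(max(from, from + which(bad)[1] - 1L - pad),
    min(to, from + which(bad)[length(which(bad))] - 1L + pad))
}

#' Reconstruct short noisy runs in a quality-assessed segment
#'
#' @param samples PPG sample vector
#' @param fs sampling rate, samples/s
#' @param quality per-window `"clean"`/`"noisy"` labels ([segment_sqa()])
#' @param window_s analysis-window length, s
#' @return list: `samples` (repaired), `quality` (updated labels),
#'   `reconstructed` (logical per window), `runs` (data.frame of repaired
#'   sample ranges; provenance record)
#' @export
reconstruct_segment <- function(samples, fs, quality, window_s = SQA_WINDOW_S) {
  nw <- length(quality)
  reconstructed <- rep(FALSE, nw)
  runs <- list()
  if (all(quality == "noisy") || !any(quality == "noisy"))
    return(list(samples = samples, quality = quality,
                reconstructed = reconstructed, runs = NULL))
  wlen <- round(window_s * fs)
  r <- rle(quality == "noisy")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  clean_win <- which(quality == "clean")
  clean_idx <- unlist(lapply(clean_win, function(w)
    ((w - 1L) * wlen + 1L):min(w * wlen, length(samples))))
  out <- samples
  for (k in which(r$values)) {
    w0 <- starts[k]; w1 <- ends[k]
    if (w0 == 1L || w1 == nw) next  # run touches a segment edge
    from <- (w0 - 1L) * wlen + 1L
    to <- min(w1 * wlen, length(samples))
    loc <- locate_noisy_run(samples, fs, from, to, clean_idx)
    if (is.null(loc)) {  # nothing localizable: treat whole flagged run
      loc <- c(from, to)
    }
    if ((loc[2] - loc[1] + 1) / fs >= PPG_RECON_MAX_S) next
    rep_sig <- synth_replacement(out, fs, loc)
    if (is.null(rep_sig)) next
    out[loc[1]:loc[2]] <- rep_sig
    reconstructed[w0:w1] <- TRUE
    quality[w0:w1] <- "clean"
    runs[[length(runs) + 1L]] <- data.frame(from = loc[1], to = loc[2])
  }
  list(samples = out, quality = quality, reconstructed = reconstructed,
       runs = if (length(runs)) do.call(rbind, runs) else NULL)
}

# build the replacement pulse train for sample range loc = c(from, to)
synth_replacement <- function(samples, fs, loc) {
  n <- length(samples)
  t0 <- (loc[1] - 1) / fs
  t1 <- (loc[2] - 1) / fs
  # clean context: up to 30 s on each side
  ctx <- round(30 * fs)
  left <- samples[max(1, loc[1] - ctx):(loc[1] - 1)]
  right <- samples[(loc[2] + 1):min(n, loc[2] + ctx)]
  pk_l <- detect_peaks_raw(left, fs) + (max(1, loc[1] - ctx) - 1) / fs
  pk_r <- detect_peaks_raw(right, fs) + loc[2] / fs
  pk_ctx <- c(pk_l, pk_r)
  ibis_ctx <- c(diff(pk_l), diff(pk_r))
  ibis_ctx <- ibis_ctx[ibis_ctx > 0.3 & ibis_ctx < 2]
  if (length(ibis_ctx) < 4 || length(pk_l) < 2) return(NULL)
  local_ibi <- median(ibis_ctx)
  dev <- ibis_ctx - mean(ibis_ctx)  # jitter pattern to mirror
  # tile beats from the last clean beat before the gap
  anchor <- max(pk_l)
  beats <- anchor
  i <- 0L
  while (beats[length(beats)] < t1 + local_ibi) {
    i <- i + 1L
    beats <- c(beats, beats[length(beats)] + local_ibi +
                 dev[(i - 1L) %% length(dev) + 1L])
  }
  beats <- beats[beats > t0 - 0.5 & beats < t1 + 0.5]
  if (!length(beats)) return(NULL)
  amp <- stats::quantile(c(left, right), 0.98, names = FALSE) -
    stats::median(c(left, right))
  base <- stats::median(c(left, right))
  d <- diff(c(beats, beats[length(beats)] + local_ibi))
  span_n <- loc[2] - loc[1] + 1L
  wave <- rep(base, span_n)
  wave <- cpp_add_pulses(wave, fs, beats - t0, rep(amp, length(beats)),
                         0.09 * sqrt(d))
  wave <- cpp_add_pulses(wave, fs, beats - t0 + 0.35 * d,
                         rep(0.35 * amp, length(beats)), 0.12 * sqrt(d))
  # linear crossfade at both boundaries
  nf <- min(round(PPG_CROSSFADE_S * fs), floor(span_n / 2))
  if (nf > 0) {
    wgt <- seq(0, 1, length.out = nf)
    wave[1:nf] <- wgt * wave[1:nf] + (1 - wgt) * samples[loc[1] - 1]
    wgt2 <- seq(1, 0, length.out = nf)
    wave[(span_n - nf + 1):span_n] <- wgt2 * wave[(span_n - nf + 1):span_n] +
      (1 - wgt2) * samples[loc[2] + 1]
  }
  wave
}
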