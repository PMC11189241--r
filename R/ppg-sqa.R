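# Signal quality assessment: classify 30-s analysis windows as clean/noisy
# from five waveform features. The decision rule is a deterministic
# threshold classifier calibrated once on a synthetic clean/noisy benchmark;
# thresholds ship as package defaults and are configurable.

SQA_WINDOW_S <- 30
SQA_CYCLE_LEN <- 40  # samples per length-normalized heart cycle

SQA_FEATURES <- c("iqr", "sd_psd", "cycle_energy_range", "mean_euclid_dist",
                  "mean_template_corr")

# cycles between consecutive peaks, resampled to a common length
cycle_matrix <- function(x, fs, peaks) {
  if (length(peaks) < 3) return(NULL)
  idx <- round(peaks * fs) + 1
  idx <- idx[idx >= 1 & idx <= length(x)]
  d <- diff(idx)
  keep <- d >= 0.3 * fs & d <= 2 * fs & d >= 4
  if (sum(keep) < 2) return(NULL)
  cpp_cycle_matrix(x, as.integer(idx[-length(idx)][keep] - 1L),
                   as.integer(d[keep]), SQA_CYCLE_LEN)
}

sqa_features_core <- function(x, fs, peaks) {
  out <- sqa_cycle_part(x, fs, peaks)
  xs <- sort(x)
  q7 <- function(p) {  # quantile type 7 on the pre-sorted vector
    h <- (length(xs) - 1) * p
    lo <- floor(h)
    xs[lo + 1] + (h - lo) * (xs[min(length(xs), lo + 2)] - xs[lo + 1])
  }
  out["iqr"] <- q7(0.75) - q7(0.25)
  xm <- x - mean(x)
  p <- Mod(fft(xm))^2 / length(x)
  out["sd_psd"] <- pop_sd(p[seq_len(floor(length(x) / 2))])
  out
}

#' Compute the five SQA features for one analysis window
#'
#' Features: interquartile range, SD of the power spectral density, range of
#' heart-cycle energies, mean Euclidean distance between length-normalized
#' cycles and their template (the pointwise mean cycle), and mean
#' template-cycle correlation. Windows with fewer than two detectable cycles
#' return degenerate features (`mean_template_corr = 0`) with a
#' `degenerate` attribute flag.
#'
#' @param window sample vector for one analysis window
#' @param fs sampling rate, samples/s
#' @return named numeric vector of the five features
#' @export
compute_sqa_features <- function(window, fs) {
  sqa_features_core(window, fs, detect_peaks_raw(window, fs))
}

#' Synthetic clean/noisy window benchmark for SQA calibration
#'
#' Generates `n` clean and `n` motion-corrupted 30-s windows with known
#' labels (a window counts as noisy when at least 10% of its samples carry
#' injected burst noise). This is the benchmark the default thresholds were
#' calibrated on.
#'
#' @param n windows per class
#' @param fs sampling rate, samples/s
#' @param seed RNG seed
#' @return list with `windows` (list of sample vectors), `label`
#'   (character, "clean"/"noisy"), `fs`
#' @export
sqa_benchmark <- function(n = 200, fs = 25, seed = 20210104) {
  seeds <- derive_seeds(seed, 4 * n)
  windows <- list(); label <- character(0)
  k <- 0L
  noisy_spec <- ppg_noise_spec(rate = 3, p_short = 1, dur_short = c(6, 25))
  i <- 0L
  while (sum(label == "clean") < n || sum(label == "noisy") < n) {
    i <- i + 1L
    if (i > length(seeds)) stop("benchmark generation did not converge")
    want_noisy <- sum(label == "noisy") < n
    set.seed(seeds[i])
    hr <- runif(1, 50, 110)
    sdms <- runif(1, 15, 70)
    s <- simulate_ppg_segment(hr, sdms, SQA_WINDOW_S, fs,
                              noise = if (want_noisy) noisy_spec else
                                ppg_noise_spec(rate = 0))
    frac <- mean(s$noise_mask)
    lab <- if (frac >= 0.1) "noisy" else if (frac == 0) "clean" else NA
    if (is.na(lab) || sum(label == lab) >= n) next
    k <- k + 1L
    windows[[k]] <- s$samples
    label <- c(label, lab)
  }
  list(windows = windows, label = label, fs = fs)
}

#' Default SQA decision thresholds
#'
#' Calibrated once on a seeded synthetic benchmark of clean and
#' motion-corrupted windows (waveform amplitude ~1); each element is the
#' cutoff in the feature's units, with `mean_template_corr` crossed
#' downwards and the rest upwards.
#'
#' @return named numeric vector
#' @export
sqa_default_thresholds <- function() {
  c(iqr = 0.8, sd_psd = 8, cycle_energy_range = 30,
    mean_euclid_dist = 3, mean_template_corr = 0.9)
}

#' Classify an analysis window as clean or noisy
#'
#' Noisy iff any feature strictly crosses its threshold in the noise
#' direction (higher for all features except `mean_template_corr`, lower for
#' that one), or the feature set is degenerate. Values exactly at the
#' threshold count as clean.
#'
#' @param features output of [compute_sqa_features()]
#' @param thresholds named cutoffs (default [sqa_default_thresholds()])
#' @param rule `"any"` (default) or `"majority"` voting over the five features
#' @return `"clean"` or `"noisy"`
#' @export
classify_quality <- function(features, thresholds = sqa_default_thresholds(),
                             rule = c("any", "majority")) {
  rule <- match.arg(rule)
  if (rule == "any") return(classify_any(features, thresholds))
  if (isTRUE(attr(features, "degenerate"))) return("noisy")
  up <- setdiff(SQA_FEATURES, "mean_template_corr")
  votes <- c(features[up] > thresholds[up],
             features["mean_template_corr"] < thresholds["mean_template_corr"])
  if (sum(votes) > length(votes) / 2) "noisy" else "clean"
}

# fast path for the default any-crossing rule
classify_any <- function(features, thresholds) {
  if (isTRUE(attr(features, "degenerate"))) return("noisy")
  noisy <- features[[1L]] > thresholds[[1L]] ||
    features[[2L]] > thresholds[[2L]] ||
    features[[3L]] > thresholds[[3L]] ||
    features[[4L]] > thresholds[[4L]] ||
    features[[5L]] < thresholds[[5L]]
  if (noisy) "noisy" else "clean"
}

#' Quality-assess every analysis window of a segment
#'
#' Provisional peaks are detected once on the full segment and shared across
#' windows.
#'
#' @param samples full-segment sample vector
#' @param fs sampling rate
#' @param window_s analysis-window length, s (default 30, non-overlapping)
#' @param thresholds SQA cutoffs
#' @return list with `quality` (character per window), `features`
#'   (windows x 5 matrix)
#' @export
segment_sqa <- function(samples, fs, window_s = SQA_WINDOW_S,
                        thresholds = sqa_default_thresholds()) {
  n <- length(samples)
  wlen <- round(window_s * fs)
  nw <- ceiling(n / wlen)
  bp <- bandpass_ppg(samples, fs)
  peaks <- detect_peaks_raw(samples, fs, bp = bp)
  feats <- matrix(NA_real_, nw, 5, dimnames = list(NULL, SQA_FEATURES))
  if (n == nw * wlen) {
    # whole-window fast path: iqr and PSD spread for all windows at once
    m <- matrix(samples, wlen, nw)
    ms <- apply(m, 2, sort)
    h <- (wlen - 1) * c(0.25, 0.75)
    lo <- floor(h)
    q <- vapply(1:2, function(k)
      ms[lo[k] + 1, ] + (h[k] - lo[k]) * (ms[lo[k] + 2, ] - ms[lo[k] + 1, ]),
      numeric(nw))
    feats[, "iqr"] <- q[, 2] - q[, 1]
    xm <- sweep(m, 2, colMeans(m))
    p <- Mod(stats::mvfft(xm))^2 / wlen
    ph <- p[seq_len(floor(wlen / 2)), , drop = FALSE]
    feats[, "sd_psd"] <- sqrt(colMeans(ph^2) - colMeans(ph)^2)
  }
  quality <- character(nw)
  for (w in seq_len(nw)) {
    i0 <- (w - 1L) * wlen + 1L
    i1 <- min(w * wlen, n)
    pk_w <- peaks[peaks >= (i0 - 1) / fs & peaks < i1 / fs] - (i0 - 1) / fs
    if (is.na(feats[w, "iqr"])) {
      f <- sqa_features_core(samples[i0:i1], fs, pk_w)
    } else {
      f <- sqa_cycle_part(samples[i0:i1], fs, pk_w)
      f[c("iqr", "sd_psd")] <- feats[w, c("iqr", "sd_psd")]
    }
    feats[w, ] <- f
    quality[w] <- classify_any(f, thresholds)
  }
  list(quality = quality, features = feats, peaks = peaks)
}

# cycle-derived SQA features only (iqr / sd_psd filled by the caller)
sqa_cycle_part <- function(x, fs, peaks) {
  out <- setNames(rep(NA_real_, 5), SQA_FEATURES)
  cyc <- cycle_matrix(x, fs, peaks)
  if (is.null(cyc)) {
    out["cycle_energy_range"] <- 0
    out["mean_euclid_dist"] <- 0
    out["mean_template_corr"] <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  cyc_c <- cyc - rowMeans(cyc)
  en <- rowSums(cyc_c^2)
  out["cycle_energy_range"] <- max(en) - min(en)
  templ <- colMeans(cyc)
  diff_t <- cyc - rep(templ, each = nrow(cyc))
  out["mean_euclid_dist"] <- mean(sqrt(rowSums(diff_t^2)))
  t_c <- templ - mean(templ)
  t_ss <- sum(t_c^2)
  if (t_ss < 1e-20) {
    out["mean_template_corr"] <- 0
  } else {
    num <- as.numeric(cyc_c %*% t_c)
    den <- sqrt(en * t_ss)
    out["mean_template_corr"] <- mean(ifelse(den < 1e-20, 0, num / den))
  }
  attr(out, "degenerate") <- FALSE
  out
}
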