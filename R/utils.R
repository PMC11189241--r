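# Shared numeric helpers.

#' Population standard deviation
#'
#' The pipeline uses the population (ddof = 0) convention for every
#' dispersion statistic so that HRV features, z-normalization and the
#' synthetic-data oracles all agree.
#'
#' @param x numeric vector; `NA`s are dropped.
#' @return population SD, or `NA_real_` if fewer than 1 finite value.
#' @export
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 1L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

#' Local maxima of a numeric series
#'
#' Strict local maxima (greater than both neighbours); plateaus return their
#' first index.
#'
#' @param x numeric vector
#' @return integer indices of local maxima (never the first or last sample)
#' @keywords internal
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # treat exact plateaus as rising edges so a flat-top peak is kept once
  s <- sign(d)
  s[s == 0] <- 1
  which(diff(s) < 0) + 1L
}

#' Welch power spectral density
#'
#' One-sided Welch PSD with Hann windows, mean-removed segments and
#' density normalisation: `sum(psd) * df` equals the series variance for a
#' single full-length segment.
#'
#' @param x numeric series (regularly sampled)
#' @param fs sampling rate in Hz
#' @param nseg segment length in samples
#' @param overlap fractional overlap between segments (default 0.5)
#' @return list with `freq` (Hz) and `psd` (x-units^2 per Hz)
#' @export
welch_psd <- function(x, fs, nseg = length(x), overlap = 0.5) {
  n <- length(x)
  nseg <- min(nseg, n)
  step <- max(1L, floor(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  u <- mean(w^2)
  nf <- floor(nseg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2 / (fs * nseg * u)
    half <- p[seq_len(nf)]
    # fold two-sided density into one-sided (not DC / Nyquist)
    if (nseg %% 2 == 0) {
      if (nf > 2L) half[2:(nf - 1L)] <- 2 * half[2:(nf - 1L)]
    } else {
      if (nf > 1L) half[2:nf] <- 2 * half[2:nf]
    }
    acc <- acc + half
  }
  list(freq = (seq_len(nf) - 1L) * fs / nseg, psd = acc / length(starts))
}

#' Integrate a PSD over a frequency band
#'
#' Rectangle rule over bins whose centre frequency falls in `[lo, hi)`.
#'
#' @param spec list with `freq`, `psd` (as from [welch_psd()])
#' @param lo,hi band edges in Hz
#' @return band power in x-units^2
#' @export
band_power <- function(spec, lo, hi) {
  df <- spec$freq[2] - spec$freq[1]
  sel <- spec$freq >= lo & spec$freq < hi
  sum(spec$psd[sel]) * df
}

#' Haversine path length over a sequence of fixes
#'
#' @param lat,lon coordinate vectors in degrees
#' @return total great-circle path length in meters (0 for < 2 fixes)
#' @export
haversine_path <- function(lat, lon) {
  n <- length(lat)
  if (n < 2L) return(0)
  sum(geosphere::distHaversine(cbind(lon[-n], lat[-n]), cbind(lon[-1], lat[-1])))
}

# Deterministic child seeds below 2^31, derived from one integer seed.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
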