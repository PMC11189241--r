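# Latent loneliness process and EMA responses.
#
# Loneliness fluctuates on two time scales: a day-level AR(1) component
# (persistence of lonely spells across days) plus a smooth within-day
# sinusoidal excursion with a random daily phase. The observed 0-100 EMA
# score is a bounded affine transform of the latent state plus response
# noise.

LATENT_AR_PHI <- 0.8          # day-to-day persistence
LATENT_WITHINDAY_AMP <- 0.3   # within-day excursion (latent SD units)
SCORE_INTERCEPT <- 50
SCORE_SLOPE <- 15             # score units per latent SD
SCORE_NOISE_SD <- 5

#' Simulate a participant's latent loneliness trajectory
#'
#' @param n_days number of study days
#' @return list with `day` (stationary AR(1), SD 1), `amp` and `phase`
#'   (within-day sinusoid parameters per day)
#' @keywords internal
simulate_latent_days <- function(n_days) {
  innov_sd <- sqrt(1 - LATENT_AR_PHI^2)
  day <- numeric(n_days)
  day[1] <- rnorm(1)
  if (n_days > 1) for (d in 2:n_days)
    day[d] <- LATENT_AR_PHI * day[d - 1] + rnorm(1, 0, innov_sd)
  list(day = day,
       amp = abs(rnorm(n_days, LATENT_WITHINDAY_AMP, 0.1)),
       phase = runif(n_days, 0, 2 * pi))
}

#' Latent state at arbitrary times of day
#'
#' @param latent result of [simulate_latent_days()]
#' @param day integer day index (1-based)
#' @param hour hour of day (0-24)
#' @return latent loneliness state (unbounded, SD ~ 1)
#' @keywords internal
latent_at <- function(latent, day, hour) {
  latent$day[day] +
    latent$amp[day] * sin(2 * pi * hour / 24 + latent$phase[day])
}

#' Map a latent state to an observed 0-100 loneliness score
#'
#' `score = clip(round(a * latent + b + eps), 0, 100)`.
#'
#' @param latent latent state vector
#' @param a,b slope and intercept of the affine map
#' @param eps_sd response-noise SD (score units)
#' @return integer scores in `[0, 100]`
#' @export
latent_to_score <- function(latent, a = SCORE_SLOPE, b = SCORE_INTERCEPT,
                            eps_sd = SCORE_NOISE_SD) {
  raw <- round(a * latent + b + rnorm(length(latent), 0, eps_sd))
  pmin(100L, pmax(0L, as.integer(raw)))
}

#' EMA prompt schedule for one day
#'
#' `ema_per_day` prompts spaced 3 h apart starting 08:00, each jittered
#' uniformly by up to 1 h into its window, so consecutive prompts are within
#' a 4-hour window of each other.
#'
#' @param ema_per_day prompts per day
#' @return list with `window_start` (hours) and `jitter_max` (hours)
#' @keywords internal
ema_schedule <- function(ema_per_day = 5) {
  list(window_start = 8 + 3 * (seq_len(ema_per_day) - 1), jitter_max = 1)
}

#' Simulate one day of EMA responses
#'
#' One response per scheduled window at a jittered prompt time; each response
#' is independently missing with probability `missing_p` (prompt ignored).
#'
#' @param latent latent trajectory ([simulate_latent_days()])
#' @param day day index
#' @param ema_per_day prompts per day
#' @param missing_p per-response missingness probability
#' @return data.table with `hour`, `latent`, `score` (NA when missed)
#' @export
simulate_ema_day <- function(latent, day, ema_per_day = 5, missing_p = 0) {
  sch <- ema_schedule(ema_per_day)
  hour <- sch$window_start + runif(ema_per_day, 0, sch$jitter_max)
  lat <- latent_at(latent, day, hour)
  score <- latent_to_score(lat)
  miss <- runif(ema_per_day) < missing_p
  score[miss] <- NA_integer_
  data.table(hour = hour, latent = lat, score = score)
}
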