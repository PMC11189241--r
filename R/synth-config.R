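# Cohort configuration for the synthetic multi-device study.

#' Coupling map between the latent loneliness process and sensed streams
#'
#' Standardized effect sizes for the channels through which the latent
#' loneliness state drives the generated data. Positive values mean the
#' channel moves in its "lonelier" direction when the latent state rises:
#' nocturnal/diurnal heart rate up, HRV (SDNN/RMSSD) down, home-stay time up,
#' number of visited places down, communication (calls/messages) down, and
#' Social-category notifications up (direction configurable by sign).
#'
#' @param nocturnal_hr,hrv,home_stay,n_places,communication,social_notifications
#'   numeric effect sizes (0 disables a channel).
#' @return named numeric vector of class `lonesense_coupling`
#' @export
coupling_map <- function(nocturnal_hr = 1, hrv = 1, home_stay = 1,
                         n_places = 1, communication = 1,
                         social_notifications = 1) {
  x <- c(nocturnal_hr = nocturnal_hr, hrv = hrv, home_stay = home_stay,
         n_places = n_places, communication = communication,
         social_notifications = social_notifications)
  if (any(!is.finite(x))) stop("coupling effect sizes must be finite")
  structure(x, class = "lonesense_coupling")
}

#' Zero-coupling (null) map: every stream is pure noise with respect to
#' the loneliness scores.
#' @return named numeric vector with all effect sizes 0
#' @export
coupling_null <- function() {
  coupling_map(0, 0, 0, 0, 0, 0)
}

#' Cohort configuration
#'
#' Defines the study conditions emulated by the generator: an 8-week style
#' protocol with 5 EMA prompts/day, 12-minute PPG segments every 2 hours,
#' day-long GPS traces with a home anchor, AWARE-style phone event logs and
#' one nightly ring summary row per participant-night.
#'
#' @param n_participants number of participants (>= 1)
#' @param n_days study length in days (>= 2)
#' @param ema_per_day EMA prompts per day (default 5)
#' @param ppg_fs PPG sampling rate, samples/s (default 25, >= 20)
#' @param ppg_segment_minutes PPG segment length, minutes (default 12)
#' @param ppg_period_hours hours between PPG segments (default 2)
#' @param coupling a [coupling_map()]
#' @param noise_burst_rate expected motion-noise bursts per PPG segment
#' @param ema_missing_p probability that a prompted EMA goes unanswered
#' @param dropout per-device daily dropout probabilities (whole-day gaps),
#'   named list with `watch`, `phone`, `ring`
#' @param seed integer RNG seed; identical config + seed reproduce the cohort
#'   byte-for-byte
#' @return list of class `cohort_config`
#' @export
cohort_config <- function(n_participants = 30, n_days = 56, ema_per_day = 5,
                          ppg_fs = 25, ppg_segment_minutes = 12,
                          ppg_period_hours = 2, coupling = coupling_map(),
                          noise_burst_rate = 0.4, ema_missing_p = 0.10,
                          dropout = list(watch = 0.07, phone = 0.05, ring = 0.10),
                          seed = 1L) {
  chk <- function(cond, field, msg) {
    if (!cond) stop(sprintf("invalid cohort config: `%s` %s", field, msg), call. = FALSE)
  }
  chk(is.numeric(n_participants) && n_participants >= 1, "n_participants", "must be >= 1")
  chk(is.numeric(n_days) && n_days >= 2, "n_days", "must be >= 2")
  chk(is.numeric(ema_per_day) && ema_per_day >= 1, "ema_per_day", "must be >= 1")
  chk(is.numeric(ppg_fs) && ppg_fs >= 20, "ppg_fs", "must be >= 20 samples/s")
  chk(ppg_segment_minutes > 0, "ppg_segment_minutes", "must be positive")
  chk(ppg_period_hours > 0 && 24 %% ppg_period_hours == 0, "ppg_period_hours",
      "must be a positive divisor of 24")
  chk(all(is.finite(unlist(coupling))), "coupling", "effect sizes must be finite")
  chk(noise_burst_rate >= 0, "noise_burst_rate", "must be >= 0")
  chk(ema_missing_p >= 0 && ema_missing_p < 1, "ema_missing_p", "must be in [0, 1)")
  structure(list(
    n_participants = as.integer(n_participants), n_days = as.integer(n_days),
    ema_per_day = as.integer(ema_per_day), ppg_fs = ppg_fs,
    ppg_segment_minutes = ppg_segment_minutes,
    ppg_period_hours = ppg_period_hours, coupling = coupling,
    noise_burst_rate = noise_burst_rate, ema_missing_p = ema_missing_p,
    dropout = dropout, seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Motion-noise specification for PPG segments
#'
#' Bursts combine large-amplitude baseline wander (0.1-0.5 Hz) with broadband
#' white noise; burst durations are drawn from a mixture that straddles the
#' 15-s reconstruction threshold so both the repair and the discard path of
#' the processing chain get exercised.
#'
#' @param rate expected bursts per segment (Poisson)
#' @param amp_wander baseline-wander amplitude (pulse amplitude is ~1)
#' @param amp_white white-noise SD inside bursts
#' @param dur_short,dur_long uniform duration ranges (s) for the two mixture
#'   components (< 15 s and >= 15 s)
#' @param p_short mixture weight of the short component
#' @return list of class `ppg_noise_spec`
#' @export
ppg_noise_spec <- function(rate = 0.4, amp_wander = 6, amp_white = 1.5,
                           dur_short = c(3, 12), dur_long = c(16, 40),
                           p_short = 0.5) {
  structure(list(rate = rate, amp_wander = amp_wander, amp_white = amp_white,
                 dur_short = dur_short, dur_long = dur_long,
                 p_short = p_short), class = "ppg_noise_spec")
}

#' Default notification category mix over the 18 app categories
#'
#' Categories follow the standard Android Play-store taxonomy used by the
#' shipped app-to-category map; Communication and Social dominate, as is
#' typical of student phone usage.
#'
#' @return named probability vector over the 18 categories (sums to 1)
#' @export
default_category_mix <- function() {
  mix <- c(
    Productivity = 0.07, Photography = 0.02, Communication = 0.25,
    Lifestyle = 0.04, `Auto & Vehicles` = 0.01, `Travel & Local` = 0.03,
    Education = 0.05, Finance = 0.03, `Video Players & Editors` = 0.05,
    Social = 0.18, `Books & Reference` = 0.02, Shopping = 0.04,
    `Health & Fitness` = 0.03, Entertainment = 0.07, Business = 0.03,
    `Music & Audio` = 0.05, Tools = 0.02, Unknown = 0.01
  )
  mix / sum(mix)
}

#' The 18 app notification categories
#' @return character vector of category names
#' @export
app_categories <- function() names(default_category_mix())
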