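# Full synthetic cohort: all device streams coupled to one latent
# loneliness process per participant, with ground truth retained.
#
# PPG waveforms are realized lazily: `simulate_cohort()` draws each
# segment's physiological parameters and a private seed, and
# `realize_ppg_segment()` reproduces the exact waveform (plus true beats
# and noise mask) on demand. This keeps a full-scale cohort (hundreds of
# millions of PPG samples) out of memory while preserving byte-level
# determinism: the same config and seed always yield the same cohort and
# the same waveforms.

STUDY_ORIGIN <- "2021-01-04 00:00:00"  # Monday; timestamps are UTC seconds from here

#' Simulate a multi-device cohort with ground truth
#'
#' Generates, per participant: a latent loneliness trajectory; EMA responses
#' (5/day by default, answered prompts only); PPG segment parameters on the
#' 12-minute/2-hour watch protocol; GPS day traces with a home anchor and
#' planted place visits; AWARE-style phone event logs; and nightly ring
#' summary rows. Whole-day device dropout gaps are injected per the config.
#'
#' @param config a [cohort_config()]
#' @param out_dir optional directory; when given the cohort tables and
#'   `ground_truth.json` are also written to disk via [write_cohort()]
#' @return list of class `lonesense_cohort` with elements `config`,
#'   `participants`, `ema`, `ppg_segments`, `gps`, `events`, `sleep`,
#'   `ground_truth`
#' @export
simulate_cohort <- function(config = cohort_config(), out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  cpl <- config$coupling
  pseeds <- derive_seeds(config$seed, config$n_participants)
  app_map <- load_app_category_map()
  seg_hours <- seq(0, 24 - config$ppg_period_hours, by = config$ppg_period_hours)
  seg_dur <- config$ppg_segment_minutes * 60

  parts <- vector("list", config$n_participants)
  ema_l <- list(); ppg_l <- list(); gps_l <- list(); ev_l <- list(); sl_l <- list()
  gt_traj <- list(); gt_geo <- list(); gt_days <- list()

  for (p in seq_len(config$n_participants)) {
    set.seed(pseeds[p])
    pid <- sprintf("P%02d", p)
    hr_base <- rnorm(1, 72, 4)
    hrv_base <- exp(rnorm(1, log(45), 0.15))  # ms
    mob_base <- runif(1, 1.5, 3)
    latent <- simulate_latent_days(config$n_days)
    geo <- simulate_geography()
    seg_seeds <- matrix(
      sample.int(.Machine$integer.max - 1L,
                 config$n_days * length(seg_hours), replace = TRUE),
      nrow = config$n_days)
    drop_watch <- runif(config$n_days) < config$dropout$watch
    drop_phone <- runif(config$n_days) < config$dropout$phone
    drop_ring <- runif(config$n_days) < config$dropout$ring

    day_gt <- vector("list", config$n_days)
    for (d in seq_len(config$n_days)) {
      lday <- latent$day[d]
      day0 <- (d - 1) * 86400

      ema <- simulate_ema_day(latent, d, config$ema_per_day, config$ema_missing_p)
      ema_l[[length(ema_l) + 1L]] <- data.table(
        participant_id = pid, day = d, timestamp = day0 + ema$hour * 3600,
        latent = ema$latent, score = ema$score)

      lat_seg <- latent_at(latent, d, seg_hours)
      mean_hr <- hr_base + 4 * cpl[["nocturnal_hr"]] * lat_seg +
        rnorm(length(seg_hours), 0, 2)
      hrv_sd <- hrv_base * exp(-0.35 * cpl[["hrv"]] * lat_seg) *
        exp(rnorm(length(seg_hours), 0, 0.10))
      ppg_l[[length(ppg_l) + 1L]] <- data.table(
        participant_id = pid, day = d,
        start_time = day0 + seg_hours * 3600, duration_s = seg_dur,
        fs = config$ppg_fs,
        mean_hr = pmin(pmax(mean_hr, 40), 180), hrv_sd_ms = hrv_sd,
        seg_seed = seg_seeds[d, ], observed = !drop_watch[d])

      if (!drop_phone[d]) {
        loc <- simulate_location_day(
          geo$home, geo$places,
          mobility_level = mob_base * exp(-0.35 * cpl[["n_places"]] * lday),
          dwell_scale = exp(-0.30 * cpl[["home_stay"]] * lday))
        gps_l[[length(gps_l) + 1L]] <- data.table(
          participant_id = pid, timestamp = day0 + loc$fixes$hour * 3600,
          lat = loc$fixes$lat, lon = loc$fixes$lon)
        ev <- simulate_events_day(
          sociability = -cpl[["communication"]] * lday,
          social_scale = exp(0.35 * cpl[["social_notifications"]] * lday))
        if (nrow(ev)) {
          ev[, `:=`(participant_id = pid, timestamp = day0 + hour * 3600)]
          ev[type == "notification",
             app_package := assign_app_package(app_category, app_map)]
          ev_l[[length(ev_l) + 1L]] <-
            ev[, .(participant_id, timestamp, type, duration_s, app_package)]
        }
        day_gt[[d]] <- list(visits = loc$visits, travel_m = loc$travel_m,
                            away_h = loc$away_h)
      } else {
        day_gt[[d]] <- list(visits = NULL, travel_m = NA_real_, away_h = NA_real_)
      }

      if (!drop_ring[d]) {
        sl <- simulate_sleep_night(lday, cpl, hr_base = hr_base - 12)
        sl[, `:=`(participant_id = pid, night = d)]
        sl_l[[length(sl_l) + 1L]] <- sl
      }
    }
    parts[[p]] <- data.table(participant_id = pid, hr_base = hr_base,
                             hrv_base = hrv_base, mob_base = mob_base,
                             tz_offset_h = 0)
    gt_traj[[pid]] <- latent
    gt_geo[[pid]] <- geo
    gt_days[[pid]] <- day_gt
  }

  ema <- rbindlist(ema_l)[!is.na(score)]
  cohort <- structure(list(
    config = config,
    participants = rbindlist(parts),
    ema = ema,
    ppg_segments = rbindlist(ppg_l),
    gps = if (length(gps_l)) rbindlist(gps_l) else NULL,
    events = if (length(ev_l)) rbindlist(ev_l) else NULL,
    sleep = if (length(sl_l)) rbindlist(sl_l) else NULL,
    ground_truth = list(coupling = cpl, trajectories = gt_traj,
                        geography = gt_geo, days = gt_days)
  ), class = "lonesense_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Reproduce a PPG segment's waveform from its cohort row
#'
#' @param cohort a `lonesense_cohort`
#' @param row integer row index into `cohort$ppg_segments`
#' @param noise optional [ppg_noise_spec()]; defaults to the config's burst rate
#' @return as [simulate_ppg_segment()]
#' @export
realize_ppg_segment <- function(cohort, row,
                                noise = ppg_noise_spec(rate = cohort$config$noise_burst_rate)) {
  r <- cohort$ppg_segments[row]
  simulate_ppg_segment(r$mean_hr, r$hrv_sd_ms, r$duration_s, r$fs,
                       noise = noise, seed = r$seg_seed)
}

# pick a concrete app package for a notification category (uniform over the
# shipped map's examples for that category)
assign_app_package <- function(categories, app_map) {
  vapply(categories, function(cat) {
    apps <- app_map$app_package[app_map$category == cat]
    if (!length(apps)) return("com.example.unknown")
    apps[sample.int(length(apps), 1)]
  }, character(1), USE.NAMES = FALSE)
}

#' Write a cohort's canonical input files
#'
#' Writes `ema.csv`, `gps.csv`, `events.csv`, `sleep.csv`, a long-format
#' `ppg_samples.csv` (all waveforms realized; intended for small cohorts)
#' and `ground_truth.json`.
#'
#' @param cohort a `lonesense_cohort`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, f) if (!is.null(x))
    write.csv(x, file.path(dir, f), row.names = FALSE)
  wr(cohort$ema, "ema.csv")
  wr(cohort$gps, "gps.csv")
  wr(cohort$events, "events.csv")
  wr(cohort$sleep, "sleep.csv")
  segs <- cohort$ppg_segments
  ppg_long <- rbindlist(lapply(seq_len(nrow(segs)), function(i) {
    s <- realize_ppg_segment(cohort, i)
    data.table(participant_id = segs$participant_id[i],
               start_time = segs$start_time[i], fs = s$fs,
               sample = round(s$samples, 6))
  }))
  wr(ppg_long, "ppg_samples.csv")
  gt <- cohort$ground_truth
  homes <- lapply(gt$geography, function(g) as.list(g$home))
  jsonlite::write_json(
    list(coupling = as.list(unclass(gt$coupling)), homes = homes,
         latent_day = lapply(gt$trajectories, function(tr) tr$day)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = 10)
  invisible(dir)
}
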