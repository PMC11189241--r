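# Synthetic behavioral streams: GPS day traces, phone event logs and
# nightly ring summaries. Geography is an abstract plane with lat/lon
# semantics: places live 0.5-3 km from home and travel legs are straight
# lines at constant speed, so the planted path length is exactly the
# haversine sum over the leg chords.

M_PER_DEG_LAT <- 111320

# offset a coordinate by (dx, dy) meters
offset_latlon <- function(lat, lon, dx, dy) {
  c(lat = lat + dy / M_PER_DEG_LAT,
    lon = lon + dx / (M_PER_DEG_LAT * cos(lat * pi / 180)))
}

#' Draw a participant's home and candidate place centroids
#'
#' @param n_places number of candidate away-from-home places
#' @return list with `home` (lat/lon) and `places` (matrix lat/lon)
#' @export
simulate_geography <- function(n_places = 6) {
  home <- c(lat = runif(1, 33.60, 33.70), lon = runif(1, -117.90, -117.80))
  ang <- runif(n_places, 0, 2 * pi)
  dist <- runif(n_places, 500, 3000)
  places <- t(vapply(seq_len(n_places), function(i)
    offset_latlon(home["lat"], home["lon"], dist[i] * cos(ang[i]),
                  dist[i] * sin(ang[i])), c(lat = 0, lon = 0)))
  list(home = home, places = places)
}

#' Simulate one day of GPS fixes
#'
#' The participant is home during 00:00-06:00, makes `~Poisson(mobility_level)`
#' visits to planted places during the day (dwell >= `dwell_min`), travels in
#' straight lines at constant speed, and is home again before midnight.
#' Fixes are sampled at a constant per-day interval of 1-5 minutes with
#' isotropic GPS jitter.
#'
#' @param home named vector `lat`/`lon`
#' @param places matrix of candidate place centroids (lat, lon)
#' @param mobility_level expected number of away visits (0 = all-home day)
#' @param dwell_scale multiplier on away dwell durations (home-stay coupling)
#' @param dwell_min minimum dwell per visit, minutes
#' @param gps_jitter_m per-coordinate GPS noise SD, meters
#' @return list with `fixes` (data.table: hour, lat, lon) and ground truth
#'   `visits` (data.table: place, start_h, end_h), `travel_m` (planted path
#'   length, meters), `away_h` (planted away time incl. travel, hours)
#' @export
simulate_location_day <- function(home, places, mobility_level,
                                  dwell_scale = 1, dwell_min = 30,
                                  gps_jitter_m = 8) {
  if (nrow(places) < 1) stop("need at least one candidate place")
  k <- min(rpois(1, mobility_level), 5L)
  fix_int_h <- runif(1, 1, 5) / 60

  # itinerary: sequence of (lat, lon, start_h, end_h, type) stays + travel legs
  speed <- runif(1, 2, 10)  # m/s for the day
  stays <- list()
  cur <- list(lat = home["lat"], lon = home["lon"], t = 0, type = 0L)
  visits <- list()
  path_m <- 0
  t_now <- 0
  day_slots <- if (k > 0) sort(runif(k, 7, 19)) else numeric(0)
  pts <- list()  # piecewise-constant/linear position timeline
  add_stay <- function(lat, lon, t0, t1) {
    pts[[length(pts) + 1L]] <<- list(lat = lat, lon = lon, t0 = t0, t1 = t1,
                                     moving = FALSE)
  }
  add_leg <- function(lat0, lon0, lat1, lon1, t0, t1) {
    pts[[length(pts) + 1L]] <<- list(lat = c(lat0, lat1), lon = c(lon0, lon1),
                                     t0 = t0, t1 = t1, moving = TRUE)
  }
  cur_lat <- unname(home["lat"]); cur_lon <- unname(home["lon"])
  for (i in seq_len(k)) {
    p <- sample.int(nrow(places), 1)
    leg_m <- geosphere::distHaversine(c(cur_lon, cur_lat),
                                      c(places[p, "lon"], places[p, "lat"]))
    t_dep <- max(t_now, day_slots[i])
    t_arr <- t_dep + leg_m / speed / 3600
    dwell_h <- max(dwell_min / 60, runif(1, 0.5, 2) * dwell_scale)
    t_leave <- t_arr + dwell_h
    if (t_leave > 22) break
    add_stay(cur_lat, cur_lon, t_now, t_dep)
    add_leg(cur_lat, cur_lon, places[p, "lat"], places[p, "lon"], t_dep, t_arr)
    add_stay(places[p, "lat"], places[p, "lon"], t_arr, t_leave)
    visits[[length(visits) + 1L]] <-
      data.table(place = p, start_h = t_arr, end_h = t_leave)
    path_m <- path_m + leg_m
    cur_lat <- places[p, "lat"]; cur_lon <- places[p, "lon"]
    t_now <- t_leave
  }
  # return home
  if (abs(cur_lat - home["lat"]) > 1e-12 || abs(cur_lon - home["lon"]) > 1e-12) {
    leg_m <- geosphere::distHaversine(c(cur_lon, cur_lat),
                                      c(home["lon"], home["lat"]))
    t_arr <- t_now + leg_m / speed / 3600
    add_leg(cur_lat, cur_lon, home["lat"], home["lon"], t_now, t_arr)
    path_m <- path_m + leg_m
    t_now <- t_arr
  }
  add_stay(unname(home["lat"]), unname(home["lon"]), t_now, 24)

  hours <- seq(0, 24 - 1e-9, by = fix_int_h)
  lat <- numeric(length(hours)); lon <- numeric(length(hours))
  for (seg in pts) {
    sel <- hours >= seg$t0 & hours < seg$t1
    if (!any(sel)) next
    if (seg$moving) {
      fr <- (hours[sel] - seg$t0) / max(seg$t1 - seg$t0, 1e-9)
      lat[sel] <- seg$lat[1] + fr * (seg$lat[2] - seg$lat[1])
      lon[sel] <- seg$lon[1] + fr * (seg$lon[2] - seg$lon[1])
    } else {
      lat[sel] <- seg$lat
      lon[sel] <- seg$lon
    }
  }
  jitter_deg <- gps_jitter_m / M_PER_DEG_LAT
  lat <- lat + rnorm(length(lat), 0, jitter_deg)
  lon <- lon + rnorm(length(lon), 0, jitter_deg / cos(mean(lat) * pi / 180))
  visits <- if (length(visits)) rbindlist(visits) else
    data.table(place = integer(0), start_h = numeric(0), end_h = numeric(0))
  away_h <- if (nrow(visits)) sum(visits$end_h - visits$start_h) else 0
  list(fixes = data.table(hour = hours, lat = lat, lon = lon),
       visits = visits, travel_m = path_m, away_h = away_h)
}

#' Simulate one day of phone events
#'
#' Poisson counts of calls (incoming/outgoing/missed/voicemail with log-normal
#' durations), messages in both directions, app notifications with category
#' drawn from `category_mix` (the Social-category rate additionally scaled by
#' `social_scale`), and screen unlock/lock session pairs. Communication rates
#' are monotone increasing in `sociability`.
#'
#' @param sociability standardized sociability state (0 = baseline)
#' @param category_mix probability vector over the 18 app categories
#' @param rates baseline daily rates (list: call_in, call_out, call_missed,
#'   voicemail, msg_in, msg_out, notifications, screen_sessions)
#' @param social_scale multiplier on the Social-category notification rate
#' @return data.table with `hour`, `type`, `duration_s`, `app_category`
#' @export
simulate_events_day <- function(sociability = 0,
                                category_mix = default_category_mix(),
                                rates = list(call_in = 3, call_out = 3,
                                             call_missed = 1, voicemail = 0.5,
                                             msg_in = 15, msg_out = 15,
                                             notifications = 60,
                                             screen_sessions = 40),
                                social_scale = 1) {
  if (abs(sum(category_mix) - 1) > 1e-6 || any(category_mix < 0))
    stop("category_mix must be a probability distribution")
  soc <- exp(0.4 * sociability)
  draw_times <- function(lambda) {
    n <- rpois(1, lambda)
    sort(runif(n, 7, 23))
  }
  ev <- list()
  add <- function(hour, type, duration_s = 0, app_category = NA_character_) {
    if (length(hour))
      ev[[length(ev) + 1L]] <<- data.table(hour = hour, type = type,
                                           duration_s = duration_s,
                                           app_category = app_category)
  }
  h <- draw_times(rates$call_in * soc)
  add(h, "call_incoming", stats::rlnorm(length(h), log(120), 0.8))
  h <- draw_times(rates$call_out * soc)
  add(h, "call_outgoing", stats::rlnorm(length(h), log(120), 0.8))
  add(draw_times(rates$call_missed), "call_missed", 0)
  h <- draw_times(rates$voicemail * soc)
  add(h, "call_voicemail", stats::rlnorm(length(h), log(30), 0.5))
  add(draw_times(rates$msg_in * soc), "message_incoming", 0)
  add(draw_times(rates$msg_out * soc), "message_outgoing", 0)
  # notifications: per-category Poisson with the Social rate scaled
  cat_rates <- rates$notifications * category_mix
  if ("Social" %in% names(cat_rates))
    cat_rates[["Social"]] <- cat_rates[["Social"]] * social_scale
  for (cat in names(cat_rates)) {
    h <- draw_times(cat_rates[[cat]])
    add(h, "notification", 0, cat)
  }
  # screen sessions: unlock + lock pairs, non-overlapping by construction
  n_scr <- rpois(1, rates$screen_sessions)
  if (n_scr > 0) {
    starts <- sort(runif(n_scr, 7, 23))
    dur_s <- stats::rlnorm(n_scr, log(90), 0.7)
    ends <- pmin(starts + dur_s / 3600, c(starts[-1], 24) - 1e-4)
    ends <- pmax(ends, starts + 1 / 3600)
    add(starts, "screen_unlock", 0)
    add(ends, "screen_lock", 0)
  }
  out <- if (length(ev)) rbindlist(ev) else
    data.table(hour = numeric(0), type = character(0),
               duration_s = numeric(0), app_category = character(0))
  setorder(out, hour)
  out[]
}

#' Simulate one nightly ring summary row
#'
#' Nocturnal heart rate and RMSSD couple to the latent loneliness state
#' (heart rate up, RMSSD down when lonelier); the remaining sleep and
#' activity fields are plausible uncoupled noise. The row is consumed as-is
#' downstream (no further feature extraction on ring data).
#'
#' @param latent_day latent loneliness state for the night
#' @param coupling a [coupling_map()]
#' @param hr_base participant nocturnal HR baseline, bpm
#' @return one-row data.table of nightly summary features
#' @export
simulate_sleep_night <- function(latent_day, coupling, hr_base = 60) {
  noct_hr <- hr_base + 3.5 * coupling[["nocturnal_hr"]] * latent_day +
    rnorm(1, 0, 1.5)
  rmssd <- 42 * exp(-0.30 * coupling[["hrv"]] * latent_day) * exp(rnorm(1, 0, 0.08))
  dur <- max(3, rnorm(1, 7.3, 0.7))
  data.table(
    sleep_duration_h = dur,
    sleep_onset_latency_min = max(1, stats::rlnorm(1, log(14), 0.5)),
    sleep_efficiency = min(0.99, max(0.6, rnorm(1, 0.9, 0.04))),
    nocturnal_hr_mean = noct_hr,
    nocturnal_hr_min = noct_hr - abs(rnorm(1, 6, 1)),
    nocturnal_rmssd = rmssd,
    activity_high_min = rpois(1, 25),
    activity_med_min = rpois(1, 70),
    activity_low_min = rpois(1, 240)
  )
}
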