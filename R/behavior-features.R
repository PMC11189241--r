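# Behavioral features from phone event logs and GPS traces.

#' Load the app-to-category map
#'
#' Two-column delimited file mapping Android package names to the 18 app
#' notification categories; the shipped default covers three example apps
#' per category. Unmapped packages fall back to "Unknown".
#'
#' @param path optional path to a custom two-column tab-separated file
#' @return data.table with `app_package`, `category`
#' @export
load_app_category_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "app_categories.tsv", package = "lonesense")
  map <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  bad <- setdiff(unique(map$category), app_categories())
  if (length(bad))
    stop("app category map contains unknown categories: ",
         paste(bad, collapse = ", "))
  map
}

GPS_HOME_RADIUS_M <- 150
GPS_GAP_MAX_S <- 600       # legs with dt > 10 min are excluded from speed stats
GPS_MOVE_SPEED_MS <- 0.5   # legs slower than this are treated as stationary jitter

#' Precompute per-fix quantities for windowed location features
#'
#' @param trace GPS trace for one participant (`timestamp`, `lat`, `lon`,
#'   optionally `speed`)
#' @param home list/vector with `lat`, `lon`
#' @param radius_m stay/home radius (m); `min_dwell_min` stay dwell (min)
#' @param min_dwell_min minimum stay dwell, minutes
#' @return list used by [location_features()]
#' @export
gps_precompute <- function(trace, home, radius_m = GPS_HOME_RADIUS_M,
                           min_dwell_min = 10) {
  trace <- as.data.table(trace)
  setorder(trace, timestamp)
  n <- nrow(trace)
  ts <- trace$timestamp
  gap <- c(pmin(diff(ts), GPS_GAP_MAX_S), 0)
  d_home <- geosphere::distHaversine(cbind(trace$lon, trace$lat),
                                     cbind(home$lon, home$lat))
  at_home <- d_home <= radius_m
  leg <- if (n > 1)
    geosphere::distHaversine(cbind(trace$lon[-n], trace$lat[-n]),
                             cbind(trace$lon[-1], trace$lat[-1])) else numeric(0)
  dt <- if (n > 1) diff(ts) else numeric(0)
  speed <- if (!is.null(trace$speed) && n > 1) trace$speed[-1] else leg / dt
  speed_ok <- dt <= GPS_GAP_MAX_S
  moving <- speed_ok & speed >= GPS_MOVE_SPEED_MS
  stays <- detect_stays(trace, radius_m, min_dwell_min)
  places <- merge_places(stays, radius_m)
  stay_place <- if (nrow(stays)) {
    # place id per stay via nearest place centroid
    vapply(seq_len(nrow(stays)), function(s) {
      d <- geosphere::distHaversine(cbind(stays$lon[s], stays$lat[s]),
                                    cbind(places$lon, places$lat))
      which.min(d)
    }, integer(1))
  } else integer(0)
  stay_home <- if (nrow(stays))
    geosphere::distHaversine(cbind(stays$lon, stays$lat),
                             cbind(home$lon, home$lat)) <= radius_m else logical(0)
  list(ts = ts, n = n,
       c_lat = cumsum(trace$lat), c_lat2 = cumsum(trace$lat^2),
       c_cov = cumsum(gap), c_home = cumsum(gap * at_home),
       # leg i joins fix i and i+1; index legs by their end fix
       leg_ts = if (n > 1) ts[-1] else numeric(0),
       c_speed = cumsum(ifelse(speed_ok, speed, 0)),
       c_speed2 = cumsum(ifelse(speed_ok, speed^2, 0)),
       c_nspeed = cumsum(as.numeric(speed_ok)),
       c_dist = cumsum(ifelse(moving, leg, 0)),
       stays = stays, stay_place = stay_place, stay_home = stay_home,
       home = home)
}

LOCATION_FEATURES <- c("lat_var", "speed_var", "speed_mean", "n_places",
                       "home_duration", "outdoor_duration",
                       "outdoor_duration_mean", "outdoor_duration_sd",
                       "longest_nonhome_stay", "travel_distance")

#' The ten location features for one time window
#'
#' Features: variance of latitude, variance and mean of speed, number of
#' places, home duration, outdoor duration, mean and SD of outdoor stay
#' duration, longest single non-home stay, and total travel distance.
#' The last four are missing-marked when the window holds fewer than two
#' places. Durations are in minutes, distance in meters, speed in m/s.
#' `home_duration + outdoor_duration` equals the covered (gap-capped)
#' window time.
#'
#' @param pre output of [gps_precompute()], or a raw trace (with `home`)
#' @param window length-2 numeric `(start, end)` in seconds
#' @param home required if `pre` is a raw trace
#' @return named numeric vector of the ten features (NA = missing-marked)
#' @export
location_features <- function(pre, window, home = NULL) {
  if (!is.list(pre) || is.null(pre$c_cov)) {
    if (is.null(home)) stop("home is required")
    pre <- gps_precompute(pre, home)
  }
  out <- setNames(rep(NA_real_, length(LOCATION_FEATURES)), LOCATION_FEATURES)
  i0 <- findInterval(window[1] - 1e-9, pre$ts) + 1L  # first fix >= start
  i1 <- findInterval(window[2] - 1e-9, pre$ts)       # last fix < end
  if (i1 < i0) return(out)
  nfix <- i1 - i0 + 1L
  rng <- function(cs, a, b) cs[b] - if (a > 1) cs[a - 1] else 0
  m_lat <- rng(pre$c_lat, i0, i1) / nfix
  out["lat_var"] <- rng(pre$c_lat2, i0, i1) / nfix - m_lat^2
  # legs indexed by end fix; use legs ending inside the window
  j0 <- findInterval(window[1], pre$leg_ts) + 1L
  j1 <- findInterval(window[2] - 1e-9, pre$leg_ts)
  if (j1 >= j0) {
    ns <- rng(pre$c_nspeed, j0, j1)
    if (ns > 0) {
      ms <- rng(pre$c_speed, j0, j1) / ns
      out["speed_mean"] <- ms
      out["speed_var"] <- rng(pre$c_speed2, j0, j1) / ns - ms^2
    }
    travel <- rng(pre$c_dist, j0, j1)
  } else travel <- 0
  covered <- rng(pre$c_cov, i0, i1)
  home_s <- rng(pre$c_home, i0, i1)
  out["home_duration"] <- home_s / 60
  out["outdoor_duration"] <- (covered - home_s) / 60

  # stays overlapping the window, clipped
  st <- pre$stays
  if (nrow(st)) {
    ov <- pmin(st$end, window[2]) - pmax(st$start, window[1])
    keep <- ov > 0
    place_ids <- unique(pre$stay_place[keep])
    out["n_places"] <- length(place_ids)
    nh <- keep & !pre$stay_home
    if (length(place_ids) >= 2L) {
      dw <- ov[nh] / 60
      out["outdoor_duration_mean"] <- mean(dw)
      out["outdoor_duration_sd"] <- pop_sd(dw)
      out["longest_nonhome_stay"] <- max(dw)
      out["travel_distance"] <- travel
    }
  } else out["n_places"] <- 0
  out
}

#' Call and message features for a time window
#'
#' Per call category (incoming, outgoing, missed, voicemail): count and
#' duration sum (missed calls have zero duration, so only their count is
#' emitted); per message direction: count. Empty windows yield zeros.
#'
#' @param log event log (`timestamp`, `type`, `duration_s`)
#' @param window length-2 numeric `(start, end)` s
#' @return named numeric vector
#' @export
comm_features <- function(log, window) {
  w <- log[timestamp >= window[1] & timestamp < window[2]]
  cnt <- function(ty) sum(w$type == ty)
  dur <- function(ty) sum(w$duration_s[w$type == ty])
  c(call_incoming_n = cnt("call_incoming"),
    call_outgoing_n = cnt("call_outgoing"),
    call_missed_n = cnt("call_missed"),
    call_voicemail_n = cnt("call_voicemail"),
    call_incoming_dur = dur("call_incoming"),
    call_outgoing_dur = dur("call_outgoing"),
    call_voicemail_dur = dur("call_voicemail"),
    message_incoming_n = cnt("message_incoming"),
    message_outgoing_n = cnt("message_outgoing"))
}

#' Notification counts per app category for a time window
#'
#' @param log event log with `app_package` for notification rows
#' @param window length-2 numeric `(start, end)` s
#' @param map app-to-category map ([load_app_category_map()])
#' @return named numeric vector over the 18 categories
#' @export
notification_features <- function(log, window, map = load_app_category_map()) {
  w <- log[type == "notification" & timestamp >= window[1] &
             timestamp < window[2]]
  cats <- map$category[match(w$app_package, map$app_package)]
  cats[is.na(cats)] <- "Unknown"
  tab <- table(factor(cats, levels = app_categories()))
  out <- as.numeric(tab)
  names(out) <- paste0("notif_", gsub("[^A-Za-z]+", "_", app_categories()))
  out
}

#' Screen usage features for a time window
#'
#' Unlock count plus total screen-on time from unlock-lock pairing after
#' sanitation: nested or duplicate unlocks are ignored while a session is
#' open, unmatched events are closed at the window edge, and sessions are
#' clipped to the window, so the duration can never exceed the window length.
#'
#' @param log event log with `screen_unlock` / `screen_lock` rows
#' @param window length-2 numeric `(start, end)` s
#' @return named numeric vector: `screen_unlock_n`, `screen_on_dur` (minutes)
#' @export
screen_features <- function(log, window, intervals = NULL) {
  iv <- intervals %||% screen_intervals(log)
  n_unl <- sum(log$type == "screen_unlock" & log$timestamp >= window[1] &
                 log$timestamp < window[2])
  on_s <- 0
  if (nrow(iv)) {
    ov <- pmin(iv$end, window[2]) - pmax(iv$start, window[1])
    on_s <- sum(ov[ov > 0])
  }
  c(screen_unlock_n = n_unl, screen_on_dur = on_s / 60)
}

#' Sanitized screen-on intervals from unlock/lock events
#'
#' @param log event log
#' @return data.table with `start`, `end` (s), non-overlapping and sorted
#' @export
screen_intervals <- function(log) {
  ev <- log[type %in% c("screen_unlock", "screen_lock")]
  setorder(ev, timestamp)
  starts <- numeric(0); ends <- numeric(0)
  open <- NA_real_
  for (i in seq_len(nrow(ev))) {
    if (ev$type[i] == "screen_unlock") {
      if (is.na(open)) open <- ev$timestamp[i]  # nested unlock ignored
    } else if (!is.na(open)) {
      starts <- c(starts, open); ends <- c(ends, ev$timestamp[i])
      open <- NA_real_
    }
  }
  if (!is.na(open)) {  # unmatched unlock: left open, clipped at window edges
    starts <- c(starts, open)
    ends <- c(ends, Inf)
  }
  data.table(start = starts, end = ends)
}
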