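# EMA-aligned windowed aggregation of device streams.
#
# Every look-back aggregation reduces to cumulative sums evaluated at
# window edges via findInterval, so building the full feature x window-grid
# value arrays stays cheap even for full-scale cohorts. Windows end AT the
# EMA timestamp (look-back only): a record may not peek past its label
# moment.

# cumulative-sum range query machinery -------------------------------------

# F(x) = sum of v for events with time < x  (times sorted)
cum_query <- function(times, v, x) {
  cs <- c(0, cumsum(v))
  cs[findInterval(x - 1e-9, times) + 1L]
}

#' Aggregate a timestamped stream over per-EMA look-back windows
#'
#' For each EMA time `t` the stream values in `[t - window, t)` are combined:
#' `"sum"` for counts and durations, `"mean"` for continuous features.
#' Empty windows yield `NA` (missing marker).
#'
#' @param stream data.table/data.frame with `timestamp` (s) and `value`
#' @param ema_times numeric vector of EMA timestamps (s)
#' @param window_hours look-back window length
#' @param how `"mean"` or `"sum"`
#' @return numeric vector, one value per EMA
#' @export
aggregate_feature <- function(stream, ema_times, window_hours,
                              how = c("mean", "sum")) {
  how <- match.arg(how)
  stopifnot(window_hours > 0)
  ts <- stream$timestamp
  o <- order(ts)
  ts <- ts[o]
  v <- stream$value[o]
  a <- ema_times - window_hours * 3600
  ok <- !is.na(v)
  n_in <- cum_query(ts, as.numeric(ok), ema_times) -
    cum_query(ts, as.numeric(ok), a)
  v0 <- ifelse(ok, v, 0)
  s <- cum_query(ts, v0, ema_times) - cum_query(ts, v0, a)
  out <- if (how == "sum") s else s / n_in
  out[n_in == 0] <- NA_real_
  out
}

# all event-derived features for one participant, vectorized over
# (ema_times x 1 window length)
event_window_features <- function(ev, iv, ema_times, window_hours, app_map,
                                  covered) {
  a <- ema_times - window_hours * 3600
  n_ema <- length(ema_times)
  out <- list()
  cnt_of <- function(times) {
    if (!length(times)) return(rep(0, n_ema))
    times <- sort(times)
    cum_query(times, rep(1, length(times)), ema_times) -
      cum_query(times, rep(1, length(times)), a)
  }
  sum_of <- function(times, vals) {
    if (!length(times)) return(rep(0, n_ema))
    o <- order(times)
    cum_query(times[o], vals[o], ema_times) - cum_query(times[o], vals[o], a)
  }
  for (ty in c("call_incoming", "call_outgoing", "call_missed",
               "call_voicemail")) {
    sel <- ev$type == ty
    out[[paste0(ty, "_n")]] <- cnt_of(ev$timestamp[sel])
    if (ty != "call_missed")
      out[[paste0(ty, "_dur")]] <- sum_of(ev$timestamp[sel], ev$duration_s[sel])
  }
  out[["message_incoming_n"]] <- cnt_of(ev$timestamp[ev$type == "message_incoming"])
  out[["message_outgoing_n"]] <- cnt_of(ev$timestamp[ev$type == "message_outgoing"])
  notif <- ev[type == "notification"]
  cats <- app_map$category[match(notif$app_package, app_map$app_package)]
  cats[is.na(cats)] <- "Unknown"
  for (cat in app_categories()) {
    nm <- paste0("notif_", gsub("[^A-Za-z]+", "_", cat))
    out[[nm]] <- cnt_of(notif$timestamp[cats == cat])
  }
  out[["screen_unlock_n"]] <- cnt_of(ev$timestamp[ev$type == "screen_unlock"])
  # screen-on time: cumulative on-time function over sanitized intervals
  scr_on <- function(x) {
    if (!nrow(iv)) return(rep(0, length(x)))
    st <- iv$start; en <- pmin(iv$end, max(x) + 1)
    dur <- en - st
    cd <- c(0, cumsum(dur))
    i <- findInterval(x, st)
    partial <- pmin(pmax(x - st[pmax(i, 1L)], 0), dur[pmax(i, 1L)])
    partial[i == 0] <- 0
    cd[pmax(i, 1L)] + partial
  }
  out[["screen_on_dur"]] <- (scr_on(ema_times) - scr_on(a)) / 60
  m <- do.call(cbind, out)
  m[!covered, ] <- NA_real_  # phone off: counts are unobserved, not zero
  m
}

# the ten location features for one participant over a set of windows
gps_window_features <- function(pre, ema_times, window_hours) {
  a <- ema_times - window_hours * 3600
  t(vapply(seq_along(ema_times), function(i)
    location_features(pre, c(a[i], ema_times[i])),
    numeric(length(LOCATION_FEATURES))))
}

#' Build the full windowed feature matrix for one look-back window length
#'
#' @param cohort a `lonesense_cohort`
#' @param hrv_stream output of [extract_hrv_stream()]
#' @param ema EMA table (`participant_id`, `timestamp`)
#' @param window_hours single window length (hours)
#' @param app_map app-to-category map
#' @return numeric matrix (EMA rows x features) with a `device` attribute
#'   tagging each column `watch`, `phone` or `ring`
#' @export
windowed_features <- function(cohort, hrv_stream, ema, window_hours,
                              app_map = load_app_category_map()) {
  pids <- unique(ema$participant_id)
  blocks <- vector("list", length(pids))
  for (k in seq_along(pids)) {
    pid <- pids[k]
    et <- ema$timestamp[ema$participant_id == pid]
    a <- et - window_hours * 3600
    # watch HRV: mean per feature over segments starting inside the window
    hs <- hrv_stream[participant_id == pid]
    hm <- sapply(HRV_FEATURES, function(f)
      aggregate_feature(data.frame(timestamp = hs$start_time, value = hs[[f]]),
                        et, window_hours, "mean"))
    colnames(hm) <- paste0("hrv_", HRV_FEATURES)
    # phone
    ev <- if (!is.null(cohort$events)) cohort$events[participant_id == pid] else
      data.table(timestamp = numeric(0), type = character(0),
                 duration_s = numeric(0), app_package = character(0))
    gp <- if (!is.null(cohort$gps)) cohort$gps[participant_id == pid] else
      data.table(timestamp = numeric(0), lat = numeric(0), lon = numeric(0))
    covered <- (cnt_in <- function(ts) {
      if (!length(ts)) return(rep(0, length(et)))
      ts <- sort(ts)
      cum_query(ts, rep(1, length(ts)), et) - cum_query(ts, rep(1, length(ts)), a)
    })(ev$timestamp) + cnt_in(gp$timestamp) > 0
    iv <- screen_intervals(ev)
    em <- event_window_features(ev, iv, et, window_hours, app_map, covered)
    gm <- if (nrow(gp) >= 3) {
      home <- tryCatch(detect_home(gp), error = function(e) NULL)
      if (is.null(home)) matrix(NA_real_, length(et), length(LOCATION_FEATURES),
                                dimnames = list(NULL, LOCATION_FEATURES))
      else gps_window_features(gps_precompute(gp, home), et, window_hours)
    } else matrix(NA_real_, length(et), length(LOCATION_FEATURES),
                  dimnames = list(NULL, LOCATION_FEATURES))
    colnames(gm) <- paste0("loc_", LOCATION_FEATURES)
    blocks[[k]] <- cbind(hm, gm, em)
  }
  m <- do.call(rbind, blocks)
  dev <- c(rep("watch", length(HRV_FEATURES)),
           rep("phone", ncol(m) - length(HRV_FEATURES)))
  attr(m, "device") <- setNames(dev, colnames(m))
  m
}

SLEEP_FEATURES <- c("sleep_duration_h", "sleep_onset_latency_min",
                    "sleep_efficiency", "nocturnal_hr_mean",
                    "nocturnal_hr_min", "nocturnal_rmssd",
                    "activity_high_min", "activity_med_min",
                    "activity_low_min")

#' Nightly ring features aligned to EMAs (most recent night's value)
#'
#' Nightly summaries are exempt from the window grid: each EMA takes the
#' most recent completed night's row (night `d` becomes available at 06:00
#' of day `d`).
#'
#' @param cohort a `lonesense_cohort`
#' @param ema EMA table
#' @return numeric matrix (EMA rows x sleep features), device `ring`
#' @export
sleep_window_features <- function(cohort, ema) {
  nm <- ifelse(startsWith(SLEEP_FEATURES, "sleep_"), SLEEP_FEATURES,
               paste0("sleep_", SLEEP_FEATURES))
  m <- matrix(NA_real_, nrow(ema), length(SLEEP_FEATURES),
              dimnames = list(NULL, nm))
  if (!is.null(cohort$sleep)) {
    for (pid in unique(ema$participant_id)) {
      sel <- ema$participant_id == pid
      sl <- cohort$sleep[participant_id == pid]
      if (!nrow(sl)) next
      setorder(sl, night)
      avail <- (sl$night - 1) * 86400 + 6 * 3600
      idx <- findInterval(ema$timestamp[sel], avail)
      vals <- as.matrix(sl[, SLEEP_FEATURES, with = FALSE])
      got <- idx > 0
      m[which(sel)[got], ] <- vals[idx[got], , drop = FALSE]
    }
  }
  attr(m, "device") <- setNames(rep("ring", ncol(m)), colnames(m))
  m
}
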