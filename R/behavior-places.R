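# Stay-point and place detection from GPS traces.
#
# Standard digital-phenotyping stay-point extraction: a stay is a maximal
# run of consecutive fixes that remains within `radius_m` of its first fix
# for at least `min_dwell_min`; stays are merged into places when their
# centroids are within `radius_m` of an existing place centroid. Home is
# the place with the greatest total dwell during the night window.

#' Extract stay points from a GPS trace
#'
#' @param trace data.table with `timestamp` (s), `lat`, `lon`, ordered in time
#' @param radius_m stay radius, meters (default 150)
#' @param min_dwell_min minimum dwell, minutes (default 10)
#' @return data.table of stays: `lat`, `lon` (centroid), `start`, `end` (s)
#' @export
detect_stays <- function(trace, radius_m = 150, min_dwell_min = 10) {
  n <- nrow(trace)
  empty <- data.table(lat = numeric(0), lon = numeric(0),
                      start = numeric(0), end = numeric(0))
  if (n < 2L) return(empty)
  ts <- trace$timestamp; la <- trace$lat; lo <- trace$lon
  stays <- list()
  i <- 1L
  while (i < n) {
    d <- geosphere::distHaversine(cbind(lo[i], la[i]),
                                  cbind(lo[(i + 1L):n], la[(i + 1L):n]))
    out <- which(d > radius_m)
    j <- if (length(out)) i + out[1L] else n + 1L  # first fix outside radius
    last_in <- j - 1L
    if (ts[last_in] - ts[i] >= min_dwell_min * 60) {
      stays[[length(stays) + 1L]] <- data.table(
        lat = mean(la[i:last_in]), lon = mean(lo[i:last_in]),
        start = ts[i], end = ts[last_in])
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (!length(stays)) return(empty)
  rbindlist(stays)
}

#' Merge stays into places
#'
#' Greedy assignment: each stay joins the first existing place whose running
#' centroid is within `radius_m`, else founds a new place.
#'
#' @param stays output of [detect_stays()]
#' @param radius_m merge radius, meters
#' @return data.table of places: `place_id`, `lat`, `lon`, `dwell_s`, and a
#'   list-column `intervals` of visit (start, end) matrices
#' @export
merge_places <- function(stays, radius_m = 150) {
  if (!nrow(stays)) {
    return(data.table(place_id = integer(0), lat = numeric(0),
                      lon = numeric(0), dwell_s = numeric(0)))
  }
  pl_lat <- numeric(0); pl_lon <- numeric(0); pl_w <- numeric(0)
  assign_id <- integer(nrow(stays))
  for (s in seq_len(nrow(stays))) {
    if (length(pl_lat)) {
      d <- geosphere::distHaversine(cbind(stays$lon[s], stays$lat[s]),
                                    cbind(pl_lon, pl_lat))
      hit <- which(d <= radius_m)
    } else hit <- integer(0)
    w <- stays$end[s] - stays$start[s]
    if (length(hit)) {
      k <- hit[1L]
      pl_lat[k] <- (pl_lat[k] * pl_w[k] + stays$lat[s] * w) / (pl_w[k] + w)
      pl_lon[k] <- (pl_lon[k] * pl_w[k] + stays$lon[s] * w) / (pl_w[k] + w)
      pl_w[k] <- pl_w[k] + w
      assign_id[s] <- k
    } else {
      pl_lat <- c(pl_lat, stays$lat[s]); pl_lon <- c(pl_lon, stays$lon[s])
      pl_w <- c(pl_w, w)
      assign_id[s] <- length(pl_lat)
    }
  }
  out <- data.table(place_id = seq_along(pl_lat), lat = pl_lat, lon = pl_lon,
                    dwell_s = pl_w)
  out$intervals <- lapply(seq_along(pl_lat), function(k)
    cbind(start = stays$start[assign_id == k], end = stays$end[assign_id == k]))
  out
}

#' Detect a participant's home
#'
#' Home is the place with the greatest total dwell among stay points falling
#' in the night window (default 00:00-06:00 local).
#'
#' @param trace GPS trace (`timestamp` s, `lat`, `lon`) for one participant
#' @param night_hours length-2 vector of local night window hours
#' @param tz_offset_h participant local-time offset from UTC, hours
#' @param radius_m,min_dwell_min stay-point parameters
#' @return list with `lat`, `lon` of home
#' @export
detect_home <- function(trace, night_hours = c(0, 6), tz_offset_h = 0,
                        radius_m = 150, min_dwell_min = 10) {
  hod <- ((trace$timestamp / 3600 + tz_offset_h) %% 24)
  night <- trace[hod >= night_hours[1] & hod < night_hours[2]]
  if (nrow(night) < 2L) stop("no night-time fixes; cannot locate home")
  if (length(unique(night$timestamp %/% 86400)) < 3L)
    stop("need fixes from at least 3 nights to locate home")
  stays <- detect_stays(night, radius_m, min_dwell_min)
  if (!nrow(stays)) stop("no night-time stay points; cannot locate home")
  places <- merge_places(stays, radius_m)
  best <- which.max(places$dwell_s)
  list(lat = places$lat[best], lon = places$lon[best])
}

#' Detect places visited inside a time window
#'
#' @param trace GPS trace for one participant
#' @param window length-2 numeric (start, end) in seconds; `NULL` = all
#' @param radius_m,min_dwell_min stay-point parameters
#' @return as [merge_places()]
#' @export
detect_places <- function(trace, window = NULL, radius_m = 150,
                          min_dwell_min = 10) {
  if (!is.null(window))
    trace <- trace[timestamp >= window[1] & timestamp < window[2]]
  merge_places(detect_stays(trace, radius_m, min_dwell_min), radius_m)
}
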