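# Behavioral features: home/place detection, location, communication,
# notification and screen features.

mk_trace <- function(hours, lat, lon)
  data.table::data.table(timestamp = hours * 3600, lat = lat, lon = lon)

test_that("home detection picks the dominant night cluster", {
  # all night fixes at one coordinate (3 nights)
  h <- rep(c(1:5, 49:53, 97:101), 1)
  tr <- mk_trace(h, rep(33.65, length(h)), rep(-117.85, length(h)))
  home <- detect_home(tr)
  expect_lt(haversine_oracle(home$lat, home$lon, 33.65, -117.85), 1)
  # 40 h night dwell beats 2 h at another cluster
  nights <- c(seq(0.5, 5.5, by = 0.25), seq(24.5, 29.5, by = 0.25),
              seq(48.5, 53.5, by = 0.25))
  other <- c(73, 73.5, 74)
  tr2 <- mk_trace(c(nights, other),
                  c(rep(33.65, length(nights)), rep(33.68, length(other))),
                  c(rep(-117.85, length(nights)), rep(-117.82, length(other))))
  home2 <- detect_home(tr2)
  expect_lt(haversine_oracle(home2$lat, home2$lon, 33.65, -117.85), 1)
  expect_error(detect_home(mk_trace(c(10, 11), c(33, 33), c(-117, -117))),
               "night")
})

test_that("place detection counts planted stays", {
  set.seed(61)
  geo <- simulate_geography()
  # stationary day at home: exactly one place
  day0 <- simulate_location_day(geo$home, geo$places, 0)
  tr <- mk_trace(day0$fixes$hour, day0$fixes$lat, day0$fixes$lon)
  expect_equal(nrow(detect_places(tr)), 1)
  # planted visits: home + distinct visited places
  repeat {
    day <- simulate_location_day(geo$home, geo$places, 3)
    if (nrow(day$visits) >= 2 && anyDuplicated(day$visits$place) == 0) break
  }
  tr2 <- mk_trace(day$fixes$hour, day$fixes$lat, day$fixes$lon)
  pl <- detect_places(tr2)
  expect_equal(nrow(pl), 1 + length(unique(day$visits$place)))
})

test_that("location features satisfy their accounting identities", {
  set.seed(62)
  geo <- simulate_geography()
  day <- simulate_location_day(geo$home, geo$places, 2)
  tr <- mk_trace(day$fixes$hour, day$fixes$lat, day$fixes$lon)
  pre <- gps_precompute(tr, as.list(geo$home))
  lf <- location_features(pre, c(0, 86400))
  # home + outdoor = covered time (gap-capped; minutes)
  fixes_per_day <- nrow(tr)
  covered <- sum(pmin(diff(tr$timestamp), 600)) / 60
  expect_equal(unname(lf["home_duration"] + lf["outdoor_duration"]), covered,
               tolerance = 1e-8)
  # all-home window: zero outdoor, distance features missing-marked
  day0 <- simulate_location_day(geo$home, geo$places, 0)
  tr0 <- mk_trace(day0$fixes$hour, day0$fixes$lat, day0$fixes$lon)
  lf0 <- location_features(gps_precompute(tr0, as.list(geo$home)), c(0, 86400))
  expect_equal(unname(lf0["outdoor_duration"]), 0, tolerance = 1e-8)
  expect_equal(unname(lf0["n_places"]), 1)
  expect_true(is.na(lf0["travel_distance"]))
  expect_true(is.na(lf0["outdoor_duration_mean"]))
  # no fixes in window: everything missing-marked
  lf_na <- location_features(pre, c(200 * 86400, 201 * 86400))
  expect_true(all(is.na(lf_na)))
  # 0.01 degrees of latitude = the haversine closed form (~1.113 km)
  tr2 <- mk_trace(c(0, 1 / 60), c(33.65, 33.66), c(-117.85, -117.85))
  lf2 <- location_features(gps_precompute(tr2, list(lat = 33.65, lon = -117.85)),
                           c(0, 600))
  skip_if(is.na(lf2["speed_mean"]))
  d_leg <- lf2["speed_mean"] * 60  # one 60-s moving leg
  expect_equal(unname(d_leg), haversine_oracle(33.65, -117.85, 33.66, -117.85),
               tolerance = 1)
})

test_that("communication and notification features count correctly", {
  log <- toy_event_log()
  cf <- comm_features(log, c(0, 86400))
  expect_equal(unname(cf["call_incoming_n"]), 2)
  expect_equal(unname(cf["call_incoming_dur"]), 90)
  expect_equal(unname(cf["call_voicemail_n"]), 1)
  expect_equal(unname(cf["message_incoming_n"]), 1)
  # empty window: all zeros
  expect_true(all(comm_features(log, c(0, 10)) == 0))
  # Table-style map: Whatsapp and Discord are Communication
  log2 <- data.table::data.table(
    participant_id = "P01", timestamp = 1:4 * 100, type = "notification",
    duration_s = 0,
    app_package = c("com.whatsapp", "com.whatsapp", "com.whatsapp",
                    "com.discord"))
  nf <- notification_features(log2, c(0, 1000))
  expect_equal(unname(nf["notif_Communication"]), 4)
  # unmapped package falls back to Unknown; totals partition the count
  log3 <- rbind(log2, data.table::data.table(
    participant_id = "P01", timestamp = 500, type = "notification",
    duration_s = 0, app_package = "com.example.foo"))
  nf3 <- notification_features(log3, c(0, 1000))
  expect_equal(unname(nf3["notif_Unknown"]), 1)
  expect_equal(sum(nf3), nrow(log3))
})

test_that("screen features pair, truncate and sanitize sessions", {
  log <- data.table::data.table(
    participant_id = "P01",
    timestamp = c(36000, 36300),
    type = c("screen_unlock", "screen_lock"), duration_s = 0,
    app_package = NA_character_)
  sf <- screen_features(log, c(30000, 40000))
  expect_equal(unname(sf["screen_unlock_n"]), 1)
  expect_equal(unname(sf["screen_on_dur"]), 5)
  # unmatched unlock truncated at the window edge
  log2 <- log[1]
  sf2 <- screen_features(log2, c(30000, 37000))
  expect_equal(unname(sf2["screen_on_dur"]), 1000 / 60)
  # nested/duplicate unlocks never exceed the interval union
  log3 <- data.table::data.table(
    participant_id = "P01",
    timestamp = c(100, 200, 300, 400, 450, 900),
    type = c("screen_unlock", "screen_unlock", "screen_lock",
             "screen_unlock", "screen_lock", "screen_lock"),
    duration_s = 0, app_package = NA_character_)
  sf3 <- screen_features(log3, c(0, 1000))
  expect_equal(unname(sf3["screen_on_dur"]) * 60, (300 - 100) + (450 - 400))
  expect_lte(sf3["screen_on_dur"] * 60, 1000)
})

test_that("windowed counts over a day partition conserve the day totals", {
  set.seed(63)
  ev <- simulate_events_day(sociability = 0.5)
  ev[, `:=`(participant_id = "P01", timestamp = hour * 3600)]
  parts <- lapply(0:5, function(k) c(k * 4, (k + 1) * 4) * 3600)
  tot <- comm_features(ev, c(0, 86400))
  by_win <- Reduce(`+`, lapply(parts, function(w) comm_features(ev, w)))
  expect_equal(by_win, tot)
  nf_tot <- notification_features(ev_with_pkg <- {
    m <- load_app_category_map()
    ev2 <- data.table::copy(ev)
    ev2[type == "notification",
        app_package := m$app_package[match(app_category, m$category)]]
    ev2
  }, c(0, 86400))
  nf_win <- Reduce(`+`, lapply(parts, function(w)
    notification_features(ev_with_pkg, w)))
  expect_equal(nf_win, nf_tot)
})
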