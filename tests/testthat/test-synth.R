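# Synthetic cohort generator: schedule arithmetic, determinism, ground
# truth and coupling behaviour.

test_that("config validation names the offending field", {
  expect_error(cohort_config(n_participants = 0), "n_participants")
  expect_error(cohort_config(n_days = 1), "n_days")
  expect_error(cohort_config(ppg_fs = 10), "ppg_fs")
  expect_error(cohort_config(coupling = coupling_map(hrv = Inf)), "finite")
})

test_that("EMA and PPG schedules follow the protocol arithmetic", {
  cfg <- cohort_config(n_participants = 2, n_days = 3, ema_missing_p = 0,
                       dropout = list(watch = 0, phone = 0, ring = 0),
                       seed = 5)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$ema), 2 * 3 * 5)
  segs_per_day <- co$ppg_segments[, .N, by = .(participant_id, day)]$N
  expect_true(all(segs_per_day == 24 / cfg$ppg_period_hours))
  # prompts within a 4-hour window of each other (plus the 1 h jitter bound)
  gaps <- co$ema[, diff(timestamp), by = .(participant_id,
                                           day = floor(timestamp / 86400))]$V1
  expect_true(all(gaps <= 4 * 3600))
})

test_that("identical config and seed give byte-identical cohort files", {
  cfg <- cohort_config(n_participants = 2, n_days = 3, seed = 99)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  simulate_cohort(cfg, out_dir = d1)
  simulate_cohort(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("PPG segment generator honours its physiological contract", {
  # zero jitter at 60 bpm: 60 +/- 1 beats, all IBIs 1000 ms
  s <- simulate_ppg_segment(60, 0, 60, 25, noise = ppg_noise_spec(rate = 0),
                            seed = 1)
  expect_true(abs(length(s$beats) - 60) <= 1)
  expect_true(all(abs(s$ibis_ms - 1000) < 1e-6))
  expect_false(any(s$noise_mask))
  # planted IBI jitter is recovered in the generated IBI spread
  sds <- vapply(1:100, function(i) {
    s <- simulate_ppg_segment(75, 40, 720, 25,
                              noise = ppg_noise_spec(rate = 0), seed = 100 + i)
    pop_sd(s$ibis_ms)
  }, numeric(1))
  expect_true(all(abs(sds - 40) / 40 < 0.15))
  # burst mixture straddles the 15-s threshold
  set.seed(8)
  masks <- replicate(60, {
    s <- simulate_ppg_segment(75, 40, 720, 25, noise = ppg_noise_spec(rate = 1))
    r <- rle(s$noise_mask)
    max(c(0, r$lengths[r$values])) / 25
  })
  expect_true(any(masks > 0 & masks < 15) && any(masks >= 15))
})

test_that("location day generator plants recoverable ground truth", {
  set.seed(21)
  geo <- simulate_geography()
  # degenerate mobility: every fix within 50 m of home
  day0 <- simulate_location_day(geo$home, geo$places, mobility_level = 0)
  d <- geosphere::distHaversine(cbind(day0$fixes$lon, day0$fixes$lat),
                                cbind(geo$home["lon"], geo$home["lat"]))
  expect_true(all(d < 50))
  expect_equal(nrow(day0$visits), 0)
  # planted visits and travel distance agree with the haversine oracle
  set.seed(22)
  day <- simulate_location_day(geo$home, geo$places, mobility_level = 3)
  expect_gt(nrow(day$visits), 0)
  tr <- data.table::data.table(timestamp = day$fixes$hour * 3600,
                               lat = day$fixes$lat, lon = day$fixes$lon)
  lf <- location_features(gps_precompute(tr, as.list(geo$home)), c(0, 86400))
  if (!is.na(lf["travel_distance"]))
    expect_lt(abs(lf["travel_distance"] - day$travel_m) / day$travel_m, 0.05)
})

test_that("event rates are Poisson at the configured intensity", {
  set.seed(31)
  mix <- setNames(c(1, rep(0, 17)), app_categories())
  counts <- replicate(1000, {
    ev <- simulate_events_day(
      sociability = 0, category_mix = mix,
      rates = list(call_in = 0, call_out = 0, call_missed = 0, voicemail = 0,
                   msg_in = 0, msg_out = 0, notifications = 10,
                   screen_sessions = 0))
    nrow(ev)
  })
  expect_gt(mean(counts), 9.4)
  expect_lt(mean(counts), 10.6)
  # point-mass category mix puts every notification in that category
  ev <- simulate_events_day(category_mix = setNames(
    as.numeric(app_categories() == "Social"), app_categories()))
  expect_true(all(ev[type == "notification"]$app_category == "Social"))
  expect_error(simulate_events_day(category_mix = c(Social = 0.5)),
               "probability")
})

test_that("EMA scores are a bounded affine map of the latent state", {
  expect_equal(latent_to_score(0, eps_sd = 0), 50L)
  expect_true(all(latent_to_score(rnorm(500, 0, 5)) %in% 0:100))
  # per-response missingness hits its configured rate
  set.seed(41)
  lat <- simulate_latent_days(2000)
  miss <- unlist(lapply(1:2000, function(d)
    is.na(simulate_ema_day(lat, d, 5, missing_p = 0.2)$score)))
  expect_gt(mean(miss), 0.19)
  expect_lt(mean(miss), 0.21)
})

test_that("couplings are monotone and vanish in the null cohort", {
  # stronger communication coupling -> stronger |cor| between daily message
  # count and daily mean score; checked across seeds at the generator level
  day_cor <- function(eff, seed) {
    co <- simulate_cohort(cohort_config(
      n_participants = 3, n_days = 12, coupling = coupling_map(
        nocturnal_hr = eff, hrv = eff, home_stay = eff, n_places = eff,
        communication = eff, social_notifications = eff),
      dropout = list(watch = 0, phone = 0, ring = 0), ema_missing_p = 0,
      seed = seed))
    ctr <- function(x, g) x - stats::ave(x, g)  # within-participant centering
    ev <- co$events[type %in% c("message_incoming", "message_outgoing")]
    msg <- ev[, .(n = .N), by = .(participant_id, day = floor(timestamp / 86400))]
    sc <- co$ema[, .(s = mean(score)),
                 by = .(participant_id, day = floor(timestamp / 86400) + 1)]
    msg[, day := day + 1]
    m <- merge(msg, sc, by = c("participant_id", "day"))
    hr <- co$ppg_segments[, .(hr = mean(mean_hr)), by = .(participant_id, day)]
    h <- merge(hr, sc, by = c("participant_id", "day"))
    c(msg = cor(ctr(m$n, m$participant_id), ctr(m$s, m$participant_id)),
      hr = cor(ctr(h$hr, h$participant_id), ctr(h$s, h$participant_id)))
  }
  rs <- vapply(1:20, function(i) day_cor(1.2, 300 + i), numeric(2))
  r0 <- vapply(1:20, function(i) day_cor(0.2, 300 + i), numeric(2))
  expect_gt(mean(abs(rs["msg", ])), mean(abs(r0["msg", ])))
  expect_gt(mean(abs(rs["hr", ])), mean(abs(r0["hr", ])))
  # null cohort: channel-score correlations stay inside a sampling band
  rn <- vapply(1:10, function(i) day_cor(0, 500 + i), numeric(2))
  n_obs <- 3 * 12
  expect_true(all(abs(rn) < 3.5 / sqrt(n_obs - 3)))
})
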