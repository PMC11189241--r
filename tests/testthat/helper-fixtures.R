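# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small strong-coupling cohort with processed HRV and assembled features
small_pipeline <- function() {
  cached("small_pipeline", {
    co <- simulate_cohort(cohort_config(n_participants = 6, n_days = 14,
                                        seed = 71))
    hrv <- extract_hrv_stream(co)
    fo <- assemble_features(co, hrv)
    list(cohort = co, hrv = hrv, features = fo)
  })
}

# a synthetic event log around a fixed day (timestamps in seconds)
toy_event_log <- function() {
  data.table::data.table(
    participant_id = "P01",
    timestamp = c(36000, 36060, 36120, 37000, 38000, 40000, 40300, 41000),
    type = c("call_incoming", "call_incoming", "call_voicemail",
             "message_incoming", "notification", "screen_unlock",
             "screen_lock", "message_outgoing"),
    duration_s = c(60, 30, 20, 0, 0, 0, 0, 0),
    app_package = c(NA, NA, NA, NA, "com.whatsapp", NA, NA, NA))
}

# planted window-selection construction: EMAs 72 h apart; an informative
# event 16 h before each EMA (value = score + noise, r ~ 0.9 at >= 24 h
# windows) and a pure-noise event 2 h before (captured by the short
# windows). Returns inputs for select_windows().
planted_window_problem <- function(n_ema = 40, sd_signal = 0.48) {
  t_ema <- (seq_len(n_ema) - 1) * 72 * 3600 + 50 * 3600
  score <- rnorm(n_ema, 50, 10)
  far <- data.frame(timestamp = t_ema - 16 * 3600,
                    value = score + rnorm(n_ema, 0, sd_signal * 10))
  near <- data.frame(timestamp = t_ema - 2 * 3600,
                     value = rnorm(n_ema, 50, 10))
  stream <- rbind(far, near)
  grid <- c(4, 8, 12, 24, 36, 48)
  vals <- vapply(grid, function(w)
    aggregate_feature(stream, t_ema, w, "mean"), numeric(n_ema))
  list(value_arrays = list(planted = vals), scores = score, grid = grid)
}
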