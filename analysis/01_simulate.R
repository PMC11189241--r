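#!/usr/bin/env Rscript
# Simulate the study cohorts: a strong-coupling cohort at the study scale
# (30 participants, ~8 weeks, 5 EMAs/day, 12-min PPG every 2 h) and a
# zero-coupling control. Writes the cohort objects for the later steps and
# a small on-disk extract of the generated streams.
#
# Usage: Rscript analysis/01_simulate.R [seed]

library(lonesense)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 11L
dir.create("results", showWarnings = FALSE)

message("Simulating strong-coupling cohort (30 participants x 56 days) ...")
cohort <- simulate_cohort(cohort_config(seed = seed))
message("  EMA responses: ", nrow(cohort$ema),
        " | PPG segments: ", nrow(cohort$ppg_segments),
        " | GPS fixes: ", nrow(cohort$gps),
        " | phone events: ", nrow(cohort$events))

message("Simulating zero-coupling control cohort (10 x 28) ...")
null_cohort <- simulate_cohort(cohort_config(
  n_participants = 10, n_days = 28, coupling = coupling_null(),
  seed = seed + 1L))

# a small fully materialized extract (all streams incl. PPG waveforms)
write_cohort(simulate_cohort(cohort_config(n_participants = 2, n_days = 2,
                                           seed = seed)),
             "results/cohort_extract")

saveRDS(list(cohort = cohort, null_cohort = null_cohort, seed = seed),
        "results/01_cohorts.rds")
message("Wrote results/01_cohorts.rds and results/cohort_extract/")
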