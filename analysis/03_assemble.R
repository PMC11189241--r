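#!/usr/bin/env Rscript
# Assemble the EMA-aligned modeling tables: per-feature optimum look-back
# windows, nightly-feature alignment, >30% missingness filter, imputation
# method selection (A: local neighbours vs B: participant mean), median-
# split labels and per-participant z-normalization.
#
# Usage: Rscript analysis/03_assemble.R

library(lonesense)

st <- readRDS("results/01_cohorts.rds")
h <- readRDS("results/02_hrv.rds")

message("Assembling strong-cohort feature table ...")
features <- assemble_features(st$cohort, h$hrv)
message("Assembling null-cohort feature table ...")
features_null <- assemble_features(st$null_cohort, h$hrv_null)

spec <- features$window_spec[order(-abs(selection_correlation))]
message("  records: ", nrow(features$table),
        " | features kept: ", length(features$device),
        " | dropped (>30% missing): ", length(features$dropped),
        " | imputation method: ", features$imputation$method)
message("  strongest window-selected features:")
print(head(spec, 8))

write.csv(features$table, "results/features.csv", row.names = FALSE)
jsonlite::write_json(
  list(window_spec = features$window_spec,
       dropped = as.list(features$dropped),
       imputation = features$imputation$method,
       label_balance = mean(features$table$label, na.rm = TRUE)),
  "results/assembly_report.json", auto_unbox = TRUE, digits = 6,
  dataframe = "rows")
saveRDS(list(features = features, features_null = features_null),
        "results/03_features.rds")
message("Wrote results/features.csv, results/assembly_report.json")
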