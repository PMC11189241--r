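#!/usr/bin/env Rscript
# Path-dependent TreeSHAP attribution for every test record of every
# personal model, aggregated to the participant x feature importance
# matrix and per-participant signed summaries.
#
# Usage: Rscript analysis/05_explain.R

library(lonesense)

fx <- readRDS("results/03_features.rds")
ev <- readRDS("results/04_eval.rds")

message("Computing TreeSHAP for all test records ...")
sh <- shap_for_eval(fx$features, ev)
x <- as.matrix(fx$features$table[, names(fx$features$device), with = FALSE])
recs <- lapply(names(sh), function(p)
  x[ev$predictions[participant_id == p]$row, , drop = FALSE])
names(recs) <- names(sh)
agg <- aggregate_importance(sh, recs)

message("Top features by cross-participant mean |SHAP|:")
print(agg$top, digits = 3)

write.csv(data.frame(participant_id = rownames(agg$matrix), agg$matrix,
                     check.names = FALSE),
          "results/shap_matrix.csv", row.names = FALSE)
write.csv(agg$signed, "results/shap_signed_summaries.csv", row.names = FALSE)
jsonlite::write_json(agg$top, "results/top_features.json",
                     auto_unbox = TRUE, digits = 6, dataframe = "rows")
message("Wrote results/shap_matrix.csv, results/top_features.json")
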