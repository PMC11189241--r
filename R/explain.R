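# Path-dependent TreeSHAP attribution for the trained ensembles.
#
# Attribution space is the lonely-class vote fraction (probability), so a
# positive value pushes the record toward the lonely class. Covers (the
# per-node training weights that define the conditional expectations) are
# recomputed by routing each tree's in-bag sample through it.

#' Extract the tree structures (with covers) from a fitted model
#'
#' @param model a `lonely_rf` from [train_model()]
#' @return list of per-tree lists: `left`, `right`, `feature` (0-based,
#'   -1/leaf markers), `threshold`, `value` (leaf = lonely-class indicator),
#'   `cover` (in-bag weighted node counts)
#' @export
forest_structure <- function(model) {
  fit <- model$fit
  x <- model$train_x
  lapply(seq_len(fit$num.trees), function(t) {
    ti <- ranger::treeInfo(fit, t)
    leaf <- ti$terminal
    left <- ifelse(leaf, -1L, ti$leftChild)
    right <- ifelse(leaf, -1L, ti$rightChild)
    feature <- ifelse(leaf, 0L, ti$splitvarID)
    threshold <- ifelse(leaf, 0, ti$splitval)
    value <- ifelse(leaf, as.numeric(as.character(ti$prediction)), 0)
    value[is.na(value)] <- 0
    inbag <- as.numeric(fit$inbag.counts[[t]])
    cover <- cpp_tree_covers(x, inbag, as.integer(left), as.integer(right),
                             as.integer(feature), as.numeric(threshold))
    list(left = as.integer(left), right = as.integer(right),
         feature = as.integer(feature), threshold = as.numeric(threshold),
         value = as.numeric(value), cover = cover)
  })
}

#' Path-dependent TreeSHAP values for a set of records
#'
#' Per-record Shapley attributions of the ensemble's vote-fraction output
#' under the cover-weighted conditional-expectation game, summed over trees.
#' Satisfies local accuracy: `base_value + rowSums(values)` equals the
#' model output for every record.
#'
#' @param model a `lonely_rf`
#' @param records feature matrix with the model's feature set
#' @return list of class `lonesense_shap`: `values` (records x features),
#'   `base_value` (scalar), `pred` (model output per record)
#' @export
tree_shap <- function(model, records) {
  records <- as.matrix(records)
  if (!identical(colnames(records), model$features))
    stop("record feature set does not match the model")
  forest <- forest_structure(model)
  res <- cpp_forest_shap(records, forest)
  colnames(res$phi) <- model$features
  structure(list(values = res$phi, base_value = res$base, pred = res$pred),
            class = "lonesense_shap")
}

#' SHAP values for every test record of an evaluation
#'
#' @param fobj the `lonesense_features` object used for the evaluation
#' @param ev a `lonesense_eval` run with `keep_models = TRUE`
#' @return named list (per participant) of `lonesense_shap` objects
#' @export
shap_for_eval <- function(fobj, ev) {
  if (is.null(ev$models)) stop("evaluation was run without keep_models = TRUE")
  x <- as.matrix(fobj$table[, names(fobj$device), with = FALSE])
  out <- list()
  for (pid in names(ev$models)) {
    rows <- ev$predictions[participant_id == pid]$row
    out[[pid]] <- tree_shap(ev$models[[pid]], x[rows, , drop = FALSE])
  }
  out
}

#' Aggregate SHAP values to a participant-by-feature importance matrix
#'
#' Mean absolute attribution per (participant, feature), features ordered
#' by their cross-participant mean; also emits a top-k table and
#' per-participant signed summaries (mean signed attribution and the
#' correlation between feature value and attribution).
#'
#' @param shap_by_participant named list of `lonesense_shap`
#' @param records_by_participant optional named list of the corresponding
#'   feature matrices (for the signed value-vs-attribution summary)
#' @param top_k number of leading features to tabulate
#' @return list: `matrix` (participants x features, mean |SHAP|, columns
#'   sorted), `ranking` (data.table), `top` (head of ranking), `signed`
#' @export
aggregate_importance <- function(shap_by_participant,
                                 records_by_participant = NULL, top_k = 20) {
  pids <- names(shap_by_participant)
  feats <- colnames(shap_by_participant[[1]]$values)
  m <- t(vapply(pids, function(p)
    colMeans(abs(shap_by_participant[[p]]$values)), numeric(length(feats))))
  rownames(m) <- pids
  ord <- order(colMeans(m), decreasing = TRUE)
  m <- m[, ord, drop = FALSE]
  ranking <- data.table(feature = colnames(m), mean_abs_shap = colMeans(m))
  signed <- rbindlist(lapply(pids, function(p) {
    sv <- shap_by_participant[[p]]$values
    dt <- data.table(participant_id = p, feature = colnames(sv),
                     mean_shap = colMeans(sv),
                     mean_abs_shap = colMeans(abs(sv)))
    if (!is.null(records_by_participant)) {
      xv <- records_by_participant[[p]]
      dt$value_attr_cor <- vapply(colnames(sv), function(f) {
        if (pop_sd(xv[, f]) < 1e-12 || pop_sd(sv[, f]) < 1e-12) return(NA_real_)
        cor(xv[, f], sv[, f])
      }, numeric(1))
    }
    dt
  }))
  list(matrix = m, ranking = ranking, top = head(ranking, top_k),
       signed = signed)
}
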