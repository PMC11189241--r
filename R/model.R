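# Per-participant temporal-holdout random-forest detection.
#
# One personal model per participant: its training set is the target's
# earliest 50% of records plus every record of all other participants; its
# test set is the target's most recent 50%. Confusion counts are pooled
# over all test rows before computing aggregate metrics. Predicted
# probability is the tree-vote fraction; the class threshold is 0.5 with
# ties going to the negative class.

RF_DEFAULTS <- list(num_trees = 100, min_node = 5, sample_fraction = 0.5,
                    seed = 20240620L)

#' Build the train/test split for one target participant
#'
#' @param tab feature table (`lonesense_features$table`)
#' @param target participant id
#' @return list: `train`, `test` (row indices into `tab`)
#' @export
make_split <- function(tab, target) {
  rows <- which(tab$participant_id == target & !is.na(tab$label))
  if (length(rows) < 4) stop("participant ", target, " has fewer than 4 labeled rows")
  rows <- rows[order(tab$ema_time[rows])]
  n_tr <- ceiling(length(rows) / 2)
  others <- which(tab$participant_id != target & !is.na(tab$label))
  list(train = c(rows[seq_len(n_tr)], others), test = rows[-seq_len(n_tr)])
}

#' Train a random-forest loneliness detector
#'
#' Randomized classification-tree ensemble (ranger backend): each tree
#' grows on a random half of the training rows (subsampling without
#' replacement), with `sqrt(p)` candidate features per split and minimum
#' node size 5, deterministically seeded. Predicted probability is the
#' fraction of trees voting for the lonely class.
#'
#' @param x feature matrix (training rows)
#' @param y integer labels (0/1)
#' @param hyper list overriding `RF_DEFAULTS`
#' @param seed RNG seed for the forest
#' @return object of class `lonely_rf`
#' @export
train_model <- function(x, y, hyper = list(), seed = RF_DEFAULTS$seed) {
  hp <- utils::modifyList(RF_DEFAULTS, hyper)
  if (length(unique(y)) < 2) stop("training labels are single-class")
  df <- as.data.frame(x)
  df$.label <- factor(y, levels = c(0, 1))
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = hp$num_trees, mtry = floor(sqrt(ncol(x))),
    min.node.size = hp$min_node, seed = seed, num.threads = 1,
    replace = FALSE, sample.fraction = hp$sample_fraction,
    keep.inbag = TRUE, respect.unordered.factors = FALSE)
  structure(list(fit = fit, features = colnames(x), train_x = as.matrix(x),
                 seed = seed), class = "lonely_rf")
}

#' Predict lonely-class vote fractions
#'
#' @param object a `lonely_rf`
#' @param newdata feature matrix with the model's feature set
#' @param ... unused
#' @return numeric vote fractions in `[0, 1]`
#' @export
predict.lonely_rf <- function(object, newdata, ...) {
  stopifnot(identical(colnames(newdata), object$features))
  pr <- stats::predict(object$fit, data = as.data.frame(newdata),
                       predict.all = TRUE, num.threads = 1)$predictions
  rowMeans(pr == 2)  # factor level 2 == lonely class
}

#' Classification metrics with pooled confusion counts
#'
#' Computes tp/fp/tn/fn, accuracy, precision, recall, F1, MSE of the binary
#' predictions (`(fp + fn) / n`, so `accuracy + mse = 1`) and rank-statistic
#' AUC with mid-ranked ties. Ratios with zero denominators are `NA` with a
#' flag.
#'
#' @param labels true 0/1 labels
#' @param predicted predicted 0/1 labels
#' @param probabilities optional scores for AUC
#' @return named list of metrics
#' @export
compute_metrics <- function(labels, predicted, probabilities = NULL) {
  if (!length(labels) || length(labels) != length(predicted))
    stop("labels and predictions must be equal-length and non-empty")
  tp <- sum(labels == 1 & predicted == 1)
  fp <- sum(labels == 0 & predicted == 1)
  tn <- sum(labels == 0 & predicted == 0)
  fn <- sum(labels == 1 & predicted == 0)
  n <- length(labels)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  auc <- NA_real_
  if (!is.null(probabilities)) {
    n1 <- sum(labels == 1); n0 <- sum(labels == 0)
    if (n1 > 0 && n0 > 0) {
      r <- rank(probabilities)  # ties mid-ranked
      auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn, n_test = n,
       accuracy = (tp + tn) / n, precision = precision, recall = recall,
       f1 = f1, mse = (fp + fn) / n, auc = auc)
}

#' Evaluate the detector over all participants
#'
#' Trains one personal model per eligible participant, predicts its test
#' rows, pools the confusion counts over all test rows, and reports pooled
#' plus per-participant metrics.
#'
#' @param fobj a `lonesense_features` object
#' @param hyper hyperparameter overrides
#' @param seed base seed; each participant's forest gets a derived seed
#' @param keep_models retain fitted models (needed for SHAP)?
#' @return list of class `lonesense_eval`: `pooled`, `per_participant`,
#'   `models` (if kept), `predictions` (data.table of test-row predictions)
#' @export
evaluate_all <- function(fobj, hyper = list(), seed = RF_DEFAULTS$seed,
                         keep_models = FALSE) {
  tab <- fobj$table
  feats <- names(fobj$device)
  x <- as.matrix(tab[, feats, with = FALSE])
  pids <- unique(tab$participant_id)
  if (length(pids) < 2) stop("need >= 2 participants")
  seeds <- derive_seeds(seed, length(pids))
  models <- list()
  preds <- list()
  per <- list()
  for (k in seq_along(pids)) {
    pid <- pids[k]
    sp <- tryCatch(make_split(tab, pid), error = function(e) NULL)
    if (is.null(sp)) next
    ytr <- tab$label[sp$train]
    if (length(unique(ytr)) < 2) next
    fit <- train_model(x[sp$train, , drop = FALSE], ytr, hyper, seeds[k])
    prob <- predict(fit, x[sp$test, , drop = FALSE])
    pred <- as.integer(prob > 0.5)  # ties to the negative class
    yte <- tab$label[sp$test]
    per[[pid]] <- compute_metrics(yte, pred, prob)
    preds[[pid]] <- data.table(participant_id = pid, row = sp$test,
                               label = yte, pred = pred, prob = prob)
    if (keep_models) models[[pid]] <- fit
  }
  if (!length(preds)) stop("no participant could be evaluated")
  allp <- rbindlist(preds)
  pooled <- compute_metrics(allp$label, allp$pred, allp$prob)
  structure(list(pooled = pooled, per_participant = per,
                 predictions = allp,
                 models = if (keep_models) models else NULL),
            class = "lonesense_eval")
}

#' Device-subset ablation
#'
#' Re-runs the full evaluation end-to-end on feature tables restricted to
#' each device subset (assembly selection steps re-run on the restricted
#' columns). Subsets with no surviving columns are skipped with a warning.
#'
#' @param fobj a `lonesense_features` object
#' @param subsets list of device-name vectors
#' @param hyper,seed passed to [evaluate_all()]
#' @return data.table, one row per subset with the pooled metrics
#' @export
evaluate_ablation <- function(fobj,
                              subsets = list("ring", "watch", "phone",
                                             c("ring", "watch", "phone")),
                              hyper = list(), seed = RF_DEFAULTS$seed) {
  rows <- lapply(subsets, function(dv) {
    sub <- tryCatch(restrict_devices(fobj, dv), error = function(e) {
      warning("subset {", paste(dv, collapse = ","), "} skipped: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(sub)) return(NULL)
    ev <- evaluate_all(sub, hyper, seed)
    data.table(devices = paste(sort(dv), collapse = "+"),
               n_features = length(sub$device),
               as.data.table(ev$pooled[c("accuracy", "precision", "recall",
                                         "f1", "mse", "auc", "n_test")]))
  })
  rbindlist(Filter(Negate(is.null), rows))
}
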