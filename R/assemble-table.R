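# Modeling-table construction: missingness filter, imputation, median-split
# labels, per-participant z-normalization, and the end-to-end assembler.

#' Drop feature columns with excessive missingness
#'
#' Columns whose pooled missing fraction strictly exceeds `threshold` are
#' dropped (a column at exactly the threshold is retained). The rule is
#' applied per feature, not per modality, because each feature has its own
#' window policy.
#'
#' @param values (rows x features) numeric matrix
#' @param threshold maximum tolerated missing fraction (default 0.30)
#' @return list: `values` (retained columns), `dropped` (named missing
#'   fractions of dropped columns)
#' @export
filter_missing <- function(values, threshold = 0.30) {
  frac <- colMeans(is.na(values))
  drop <- frac > threshold
  if (all(drop)) stop("all feature columns exceed the missing-data threshold")
  list(values = values[, !drop, drop = FALSE], dropped = frac[drop])
}

# method A for one participant's column: mean of up to two nearest
# preceding and two nearest succeeding valid values (rows are in temporal
# order within participant)
impute_A_series <- function(x) {
  miss <- which(is.na(x))
  if (!length(miss)) return(x)
  ok <- which(!is.na(x))
  if (!length(ok)) return(x)
  for (i in miss) {
    before <- tail(ok[ok < i], 2)
    after <- head(ok[ok > i], 2)
    nb <- c(before, after)
    if (length(nb)) x[i] <- mean(x[nb])
  }
  x
}

#' Impute missing feature values
#'
#' Method A replaces a missing value with the mean of that participant's up
#' to two nearest preceding and two nearest succeeding valid samples; method
#' B with the mean of all of that participant's valid values. Observed
#' values are never altered. A participant with no valid value in a column
#' is left `NA` here (filled later from the pooled training mean, flagged).
#'
#' @param values (rows x features) matrix, rows temporally ordered within
#'   participant
#' @param participant participant id per row
#' @param method `"A"` or `"B"`
#' @return imputed matrix
#' @export
impute_values <- function(values, participant, method = c("B", "A")) {
  method <- match.arg(method)
  out <- values
  for (pid in unique(participant)) {
    rows <- which(participant == pid)
    sub <- values[rows, , drop = FALSE]
    has_na <- which(colSums(is.na(sub)) > 0)
    for (j in has_na) {
      x <- sub[, j]
      if (method == "A") {
        out[rows, j] <- impute_A_series(x)
      } else {
        m <- mean(x, na.rm = TRUE)
        x[is.na(x)] <- if (is.nan(m)) NA_real_ else m
        out[rows, j] <- x
      }
    }
  }
  out
}

#' Median-split loneliness labels per participant
#'
#' Label 1 (lonely) iff the score strictly exceeds that participant's median
#' score; scores at the median go to the not-lonely class. Participants with
#' constant scores get all-`NA` labels (excluded from modeling) with a
#' warning.
#'
#' @param scores loneliness scores (0-100)
#' @param participant participant id per row
#' @return integer labels (0/1, `NA` for excluded participants)
#' @export
make_labels <- function(scores, participant) {
  lab <- rep(NA_integer_, length(scores))
  for (pid in unique(participant)) {
    rows <- participant == pid
    s <- scores[rows]
    if (length(unique(s)) < 2) {
      warning("participant ", pid, " has constant scores; excluded from modeling")
      next
    }
    lab[rows] <- as.integer(s > median(s))
  }
  lab
}

#' Per-participant z-normalization from training rows
#'
#' For every (participant, feature) pair the mean and population SD are
#' estimated from that participant's training rows only and applied to all
#' of that participant's rows. Degenerate columns (SD < 1e-8) are scaled by
#' 1 and flagged.
#'
#' @param values (rows x features) matrix
#' @param participant participant id per row
#' @param is_test logical test-row indicator (training rows = `!is_test`)
#' @return list: `values` (normalized), `degenerate` (data.table of flagged
#'   participant/feature pairs)
#' @export
znormalize_split <- function(values, participant, is_test) {
  out <- values
  flags <- list()
  for (pid in unique(participant)) {
    rows <- which(participant == pid)
    tr <- rows[!is_test[rows]]
    if (!length(tr)) stop("participant ", pid, " has no training rows")
    mu <- colMeans(values[tr, , drop = FALSE], na.rm = TRUE)
    sdv <- apply(values[tr, , drop = FALSE], 2, pop_sd)
    deg <- !is.na(sdv) & sdv < 1e-8
    if (any(deg))
      flags[[length(flags) + 1L]] <- data.table(participant_id = pid,
                                                feature = colnames(values)[deg])
    sdv[deg | is.na(sdv)] <- 1
    out[rows, ] <- sweep(sweep(values[rows, , drop = FALSE], 2, mu), 2, sdv, "/")
  }
  list(values = out,
       degenerate = if (length(flags)) rbindlist(flags) else NULL)
}

#' Assemble the EMA-aligned modeling table
#'
#' Runs the full dataset-assembly chain: windowed aggregation over the
#' candidate grid, per-feature optimum-window selection, nightly-feature
#' alignment, missingness filtering, imputation-method selection and
#' imputation, per-participant median-split labels, temporal train/test
#' flags and per-participant z-normalization. All selection steps use only
#' each participant's earliest-half rows (training rows of every personal
#' model).
#'
#' @param cohort a `lonesense_cohort`
#' @param hrv_stream optional precomputed [extract_hrv_stream()] output
#' @param grid candidate window lengths, hours
#' @param median_mode `"full"` (median over the participant's whole score
#'   series) or `"train"` (leakage-safe train-only median)
#' @return list of class `lonesense_features`: `table` (data.table with
#'   `participant_id`, `ema_time`, `score`, `label`, `is_test` and the
#'   normalized feature columns), `device` (named device tag per feature),
#'   `window_spec`, `imputation`, `dropped`, `raw` (pre-imputation values)
#' @export
assemble_features <- function(cohort, hrv_stream = NULL,
                              grid = WINDOW_GRID_H,
                              median_mode = c("full", "train")) {
  median_mode <- match.arg(median_mode)
  ema <- data.table::copy(cohort$ema)
  setorder(ema, participant_id, timestamp)
  if (is.null(hrv_stream)) hrv_stream <- extract_hrv_stream(cohort)
  app_map <- load_app_category_map()

  mats <- lapply(grid, function(w)
    windowed_features(cohort, hrv_stream, ema, w, app_map))
  dev_win <- attr(mats[[1]], "device")
  feats <- colnames(mats[[1]])
  value_arrays <- lapply(setNames(feats, feats), function(f)
    do.call(cbind, lapply(mats, function(m) m[, f])))

  # train/test flags: earliest ceil(n/2) rows per participant are training
  is_test <- logical(nrow(ema))
  for (pid in unique(ema$participant_id)) {
    rows <- which(ema$participant_id == pid)
    is_test[rows[seq_along(rows) > ceiling(length(rows) / 2)]] <- TRUE
  }
  sel_rows <- which(!is_test)

  spec <- select_windows(value_arrays, ema$score, sel_rows, grid)
  chosen <- vapply(seq_len(nrow(spec)), function(i)
    value_arrays[[spec$feature[i]]][, match(spec$window_hours[i], grid)],
    numeric(nrow(ema)))
  colnames(chosen) <- spec$feature
  slp <- sleep_window_features(cohort, ema)
  values <- cbind(chosen, slp)
  device <- c(dev_win[colnames(chosen)], attr(slp, "device"))

  filt <- filter_missing(values)
  values <- filt$values
  device <- device[colnames(values)]

  imp_sel <- select_imputation(values, ema$participant_id, ema$score, sel_rows)
  imputed <- impute_values(values, ema$participant_id, imp_sel$method)
  # pooled-training-mean fallback for participants with no valid values
  pooled_flag <- NULL
  if (anyNA(imputed)) {
    pooled <- colMeans(imputed[sel_rows, , drop = FALSE], na.rm = TRUE)
    nas <- which(is.na(imputed), arr.ind = TRUE)
    imputed[nas] <- pooled[nas[, 2]]
    pooled_flag <- unique(colnames(imputed)[nas[, 2]])
  }

  label <- if (median_mode == "full") make_labels(ema$score, ema$participant_id)
  else {
    lab <- rep(NA_integer_, nrow(ema))
    for (pid in unique(ema$participant_id)) {
      rows <- which(ema$participant_id == pid)
      m <- median(ema$score[rows[!is_test[rows]]])
      lab[rows] <- as.integer(ema$score[rows] > m)
    }
    lab
  }

  zn <- znormalize_split(imputed, ema$participant_id, is_test)
  tab <- data.table(participant_id = ema$participant_id,
                    ema_time = ema$timestamp, score = ema$score,
                    label = label, is_test = is_test)
  tab <- cbind(tab, as.data.table(zn$values))
  structure(list(table = tab, device = device, window_spec = spec,
                 imputation = imp_sel, dropped = filt$dropped,
                 raw = values, degenerate = zn$degenerate,
                 pooled_fallback = pooled_flag),
            class = "lonesense_features")
}

#' Rebuild a feature table restricted to a device subset
#'
#' Re-runs the post-selection assembly steps (missingness filter,
#' imputation-method vote, imputation, normalization) on the columns
#' originating from the given devices; per-feature window selection is
#' unchanged by construction since it is independent across features.
#'
#' @param fobj a `lonesense_features` object
#' @param devices character subset of `c("ring", "watch", "phone")`
#' @return a `lonesense_features` object over the restricted columns
#' @export
restrict_devices <- function(fobj, devices) {
  keep <- names(fobj$device)[fobj$device %in% devices]
  if (!length(keep)) stop("no feature columns for device subset")
  values <- fobj$raw[, keep, drop = FALSE]
  tab <- fobj$table
  sel_rows <- which(!tab$is_test)
  imp_sel <- select_imputation(values, tab$participant_id, tab$score, sel_rows)
  imputed <- impute_values(values, tab$participant_id, imp_sel$method)
  if (anyNA(imputed)) {
    pooled <- colMeans(imputed[sel_rows, , drop = FALSE], na.rm = TRUE)
    nas <- which(is.na(imputed), arr.ind = TRUE)
    imputed[nas] <- pooled[nas[, 2]]
  }
  zn <- znormalize_split(imputed, tab$participant_id, tab$is_test)
  out <- fobj
  out$table <- cbind(tab[, .(participant_id, ema_time, score, label, is_test)],
                     as.data.table(zn$values))
  out$device <- fobj$device[keep]
  out$raw <- values
  out$imputation <- imp_sel
  out
}
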