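# Per-feature optimum-window selection and imputation-method selection.
# Both selections use training rows only (each participant's earliest-half
# records, which are in the training set of every personal model), so no
# test row of any model can influence them.

WINDOW_GRID_H <- c(4, 8, 12, 24, 36, 48)

#' Select the optimum look-back window for each feature
#'
#' For each feature, the Pearson correlation (pairwise-complete) between
#' its aggregated values and the continuous loneliness scores is computed
#' per candidate window over the selection rows; the window with the
#' largest `|r|` wins, ties going to the shorter window. Features whose
#' correlation is undefined at every window (constant or all-missing)
#' default to 24 h and are flagged.
#'
#' @param value_arrays named list: feature -> (EMA rows x windows) matrix
#' @param scores continuous loneliness scores (0-100), one per EMA row
#' @param sel_rows logical/integer rows to use (training portion)
#' @param grid candidate window lengths, hours
#' @return data.table: `feature`, `window_hours`, `selection_correlation`,
#'   `flagged`
#' @export
select_windows <- function(value_arrays, scores, sel_rows = NULL,
                           grid = WINDOW_GRID_H) {
  if (is.null(sel_rows)) sel_rows <- seq_along(scores)
  sc <- scores[sel_rows]
  if (length(unique(sc)) < 2) stop("need >= 2 distinct scores to select windows")
  out <- lapply(names(value_arrays), function(f) {
    vm <- value_arrays[[f]][sel_rows, , drop = FALSE]
    r <- vapply(seq_len(ncol(vm)), function(j) {
      v <- vm[, j]
      ok <- !is.na(v)
      if (sum(ok) < 3 || pop_sd(v[ok]) < 1e-12) return(NA_real_)
      suppressWarnings(cor(v[ok], sc[ok]))
    }, numeric(1))
    if (all(is.na(r))) {
      data.table(feature = f, window_hours = 24,
                 selection_correlation = NA_real_, flagged = TRUE)
    } else {
      best <- which(abs(r) == max(abs(r), na.rm = TRUE))[1L]  # ties: shorter
      data.table(feature = f, window_hours = grid[best],
                 selection_correlation = r[best], flagged = FALSE)
    }
  })
  rbindlist(out)
}

#' Choose the imputation method (A vs B) by training-set correlation
#'
#' Each feature column is imputed under method A (nearest two preceding and
#' succeeding valid samples) and method B (participant mean of all valid
#' values); the method with the higher `|r|` against the loneliness scores
#' on the selection rows wins that feature's vote, and the majority method
#' is applied to all features. Ties (including the no-missing-data case)
#' go to B.
#'
#' @param values (EMA rows x features) matrix at the chosen windows
#' @param participant participant id per row
#' @param scores loneliness scores per row
#' @param sel_rows selection (training) rows
#' @return list: `method` ("A"/"B"), `votes` (named vector of per-feature
#'   winners)
#' @export
select_imputation <- function(values, participant, scores, sel_rows = NULL) {
  if (is.null(sel_rows)) sel_rows <- seq_len(nrow(values))
  va <- impute_values(values, participant, "A")
  vb <- impute_values(values, participant, "B")
  sc <- scores[sel_rows]
  vote <- vapply(seq_len(ncol(values)), function(j) {
    r_of <- function(v) {
      v <- v[sel_rows]
      ok <- !is.na(v)
      if (sum(ok) < 3 || pop_sd(v[ok]) < 1e-12) return(NA_real_)
      abs(suppressWarnings(cor(v[ok], sc[ok])))
    }
    ra <- r_of(va[, j]); rb <- r_of(vb[, j])
    if (is.na(ra) || is.na(rb) || ra == rb) "B" else if (ra > rb) "A" else "B"
  }, character(1))
  names(vote) <- colnames(values)
  method <- if (sum(vote == "A") > length(vote) / 2) "A" else "B"
  list(method = method, votes = vote)
}
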