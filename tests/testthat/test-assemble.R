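# Dataset assembly: aggregation, window selection, missingness handling,
# labels and normalization.

test_that("look-back aggregation sums counts and averages values", {
  ema <- c(10, 20) * 3600
  stream <- data.frame(timestamp = 9 * 3600, value = 5)
  expect_equal(aggregate_feature(stream, ema, 4, "mean"), c(5, NA))
  s2 <- data.frame(timestamp = c(8, 9) * 3600, value = c(2, 3))
  expect_equal(aggregate_feature(s2, ema, 4, "sum"), c(5, NA))
  # the window is [t - w, t): a value at exactly t is excluded
  s3 <- data.frame(timestamp = 10 * 3600, value = 7)
  expect_true(is.na(aggregate_feature(s3, ema, 4, "mean")[1]))
})

test_that("window selection recovers the planted optimum", {
  set.seed(81)
  pr <- planted_window_problem()
  spec <- select_windows(pr$value_arrays, pr$scores, grid = pr$grid)
  expect_equal(spec$window_hours, 24)
  expect_gt(abs(spec$selection_correlation), 0.5)
  # constant feature: undefined correlation, defaulted and flagged
  const <- list(flat = matrix(1, length(pr$scores), 6))
  spec2 <- select_windows(const, pr$scores, grid = pr$grid)
  expect_equal(spec2$window_hours, 24)
  expect_true(spec2$flagged)
  # anti-correlated features win on |r|
  anti <- list(neg = vapply(1:6, function(j)
    if (j == 2) -pr$scores + rnorm(length(pr$scores), 0, 2)
    else rnorm(length(pr$scores)), numeric(length(pr$scores))))
  spec3 <- select_windows(anti, pr$scores, grid = pr$grid)
  expect_equal(spec3$window_hours, pr$grid[2])
  expect_lt(spec3$selection_correlation, -0.9)
})

test_that("missingness filter applies the strict 30% boundary per feature", {
  v <- cbind(a = c(rep(NA, 31), rnorm(69)),
             b = c(rep(NA, 30), rnorm(70)),
             c = rnorm(100))
  out <- filter_missing(v, 0.30)
  expect_named(out$dropped, "a")
  expect_identical(colnames(out$values), c("b", "c"))
  expect_error(filter_missing(cbind(x = rep(NA_real_, 5))), "threshold")
})

test_that("imputation methods match their worked examples", {
  p <- rep("P01", 5)
  a <- impute_values(cbind(f = c(1, 2, NA, 4, 5)), p, "A")
  expect_equal(unname(a[3, 1]), 3)
  a2 <- impute_values(cbind(f = c(NA, 7)), rep("P01", 2), "A")
  expect_equal(unname(a2[1, 1]), 7)
  b <- impute_values(cbind(f = c(2, 4, NA, 6)), rep("P01", 4), "B")
  expect_equal(unname(b[3, 1]), 4)
  # observed values are never altered
  x <- cbind(f = c(1, NA, 3, NA, 9))
  for (m in c("A", "B")) {
    got <- impute_values(x, rep("P01", 5), m)
    expect_identical(got[c(1, 3, 5), 1], x[c(1, 3, 5), 1])
  }
})

test_that("imputation-method selection votes per feature with B on ties", {
  set.seed(82)
  n <- 60
  p <- rep("P01", n)
  # a smooth score trajectory makes neighbouring samples informative, so
  # method A's local mean preserves the signal at the gaps while method B's
  # constant participant mean dilutes it -> A wins this feature's vote
  score <- 50 + 10 * sin(seq(0, 6 * pi, length.out = n)) + rnorm(n, 0, 1)
  f_a <- score + rnorm(n, 0, 1)
  f_a[seq(3, n, by = 4)] <- NA
  # complete features tie (A and B imputations are identical) and tie -> B
  f_b <- rnorm(n)
  sel <- select_imputation(cbind(fa = f_a, fb = f_b, fc = f_b + score / 20),
                           p, score)
  expect_identical(unname(sel$votes[["fa"]]), "A")
  expect_identical(unname(sel$votes[["fb"]]), "B")
  # majority of B-votes -> B applied everywhere
  expect_identical(sel$method, "B")
  # no missing data: A and B identical, B reported
  sel2 <- select_imputation(cbind(x = score, y = rev(score)), p, score)
  expect_identical(sel2$method, "B")
})

test_that("median-split labels follow the strict tie rule", {
  expect_equal(make_labels(c(10, 20, 30, 40), rep("P1", 4)), c(0L, 0L, 1L, 1L))
  expect_equal(make_labels(c(50, 50, 50, 80), rep("P1", 4)), c(0L, 0L, 0L, 1L))
  expect_warning(lab <- make_labels(c(5, 5, 5, 5), rep("P1", 4)), "constant")
  expect_true(all(is.na(lab)))
  # continuous scores: prevalence 0.5 within 1/n
  set.seed(83)
  s <- rnorm(400)
  lab2 <- make_labels(s, rep("P1", 400))
  expect_lte(abs(mean(lab2) - 0.5), 1 / 400 + 1e-12)
})

test_that("z-normalization uses each participant's training rows only", {
  v <- cbind(f = c(1, 3, 10, 2, 2, 7))
  p <- c("A", "A", "A", "B", "B", "B")
  is_test <- c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE)
  zn <- znormalize_split(v, p, is_test)
  expect_equal(unname(zn$values[1:2, 1]), c(-1, 1))  # {1,3} -> population SD 1
  expect_equal(unname(zn$values[3, 1]), 8)           # test row, train stats
  expect_equal(unname(zn$values[4:5, 1]), c(0, 0))   # constant training column
  expect_equal(zn$degenerate$participant_id, "B")
  # a test value equal to the training mean maps to zero
  v2 <- cbind(g = c(2, 4, 3))
  zn2 <- znormalize_split(v2, rep("A", 3), c(FALSE, FALSE, TRUE))
  expect_equal(unname(zn2$values[3, 1]), 0)
})

test_that("assembled tables are normalized, complete and leakage-free", {
  sp <- small_pipeline()
  fo <- sp$features
  tab <- fo$table
  feats <- names(fo$device)
  # no missing values remain in retained columns
  expect_false(anyNA(tab[, feats, with = FALSE]))
  # one row per retained EMA, no duplication
  expect_equal(nrow(tab), nrow(sp$cohort$ema))
  expect_false(any(duplicated(tab[, .(participant_id, ema_time)])))
  # per-participant training columns have mean 0, population SD 1
  for (pid in unique(tab$participant_id)[1:3]) {
    tr <- tab[participant_id == pid & !is_test]
    m <- as.matrix(tr[, feats, with = FALSE])
    mu <- colMeans(m)
    sdv <- apply(m, 2, pop_sd)
    nondeg <- !(colnames(m) %in% fo$degenerate$feature[
      fo$degenerate$participant_id == pid])
    expect_true(all(abs(mu[nondeg]) < 1e-9))
    expect_true(all(abs(sdv[nondeg] - 1) < 1e-9))
  }
  # selections use training rows only: shuffling test-row scores changes
  # neither the window choice nor the imputation method
  arrays <- lapply(setNames(feats[1:5], feats[1:5]), function(f)
    matrix(rep(fo$raw[, f], 6), ncol = 6))
  sc <- tab$score
  sc2 <- sc
  sc2[tab$is_test] <- sample(sc2[tab$is_test])
  sel_rows <- which(!tab$is_test)
  s1 <- select_windows(arrays, sc, sel_rows)
  s2 <- select_windows(arrays, sc2, sel_rows)
  expect_identical(s1, s2)
})
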