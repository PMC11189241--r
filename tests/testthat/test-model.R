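# Per-participant temporal split, forest training, metrics, ablation.

mk_tab <- function(n_per, pids = c("A", "B")) {
  data.table::rbindlist(lapply(pids, function(p)
    data.table::data.table(participant_id = p, ema_time = seq_len(n_per),
                           score = 50, label = rep_len(c(0L, 1L), n_per),
                           is_test = FALSE)))
}

test_that("temporal split sends the earliest ceiling-half to training", {
  tab <- mk_tab(6)
  sp <- make_split(tab, "A")
  expect_equal(sort(tab$ema_time[setdiff(sp$train, 7:12)]), 1:3)
  expect_equal(sort(tab$ema_time[sp$test]), 4:6)
  # 2 participants x 10 rows: |train| = 5 + 10, |test| = 5
  tab2 <- mk_tab(10)
  sp2 <- make_split(tab2, "A")
  expect_length(sp2$train, 15)
  expect_length(sp2$test, 5)
  # odd n: ceiling goes to training
  tab3 <- mk_tab(5)
  sp3 <- make_split(tab3, "A")
  expect_length(intersect(sp3$train, which(tab3$participant_id == "A")), 3)
  expect_length(sp3$test, 2)
  expect_error(make_split(mk_tab(3), "A"), "fewer than 4")
  # temporal ordering: max train time < min test time for the target
  expect_lt(max(tab$ema_time[setdiff(sp$train, 7:12)]),
            min(tab$ema_time[sp$test]))
})

test_that("forest training is deterministic and separates separable data", {
  set.seed(91)
  x <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.integer(x[, 1] > 0)
  m <- train_model(x, y, seed = 7)
  expect_equal(as.integer(predict(m, x) > 0.5), y)
  m2 <- train_model(x, y, seed = 7)
  expect_identical(predict(m, x), predict(m2, x))
  expect_error(train_model(x, rep(1L, 100)), "single-class")
  # prediction of a row does not depend on which other rows are scored
  p_all <- predict(m, x[1:10, ])
  p_one <- predict(m, x[1:2, ])
  expect_identical(p_all[1:2], p_one)
})

test_that("metrics match the worked confusion example and identities", {
  # tp=3, fp=1, fn=2, tn=4
  labels <- c(rep(1, 5), rep(0, 5))
  pred <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  m <- compute_metrics(labels, pred)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35, tolerance = 1e-12)
  expect_equal(m$mse, 0.3)
  expect_equal(m$accuracy + m$mse, 1)
  # perfect predictions
  mp <- compute_metrics(labels, labels, probabilities = labels)
  expect_equal(mp$accuracy, 1)
  expect_equal(mp$mse, 0)
  expect_equal(mp$f1, 1)
  expect_equal(mp$auc, 1)
  # degenerate denominators are missing-marked
  m0 <- compute_metrics(c(0, 0), c(0, 0))
  expect_true(is.na(m0$precision))
  expect_error(compute_metrics(integer(0), integer(0)), "non-empty")
})

test_that("AUC sits at chance under label permutation", {
  set.seed(92)
  auc <- replicate(30, {
    lab <- sample(rep(0:1, each = 150))
    compute_metrics(lab, lab, probabilities = runif(300))$auc
  })
  expect_lt(abs(mean(auc) - 0.5), 0.05)
  expect_true(all(abs(auc - 0.5) < 0.15))
})

test_that("pooled evaluation and ablation behave on the small cohort", {
  sp <- small_pipeline()
  ev <- evaluate_all(sp$features, seed = 101)
  expect_equal(ev$pooled$accuracy + ev$pooled$mse, 1)
  expect_equal(ev$pooled$n_test, nrow(ev$predictions))
  # f1 is the harmonic mean of precision and recall
  expect_equal(ev$pooled$f1,
               2 / (1 / ev$pooled$precision + 1 / ev$pooled$recall),
               tolerance = 1e-12)
  # a phone-only subset carries no HRV or sleep columns
  ph <- restrict_devices(sp$features, "phone")
  expect_false(any(grepl("^(hrv|sleep)_", names(ph$device))))
  ab <- evaluate_ablation(sp$features, seed = 101)
  expect_equal(nrow(ab), 4)
  expect_true(all(c("accuracy", "precision", "recall", "f1", "mse", "auc")
                  %in% names(ab)))
  expect_true(all(abs(ab$accuracy + ab$mse - 1) < 1e-12))
})
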