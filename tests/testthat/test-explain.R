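# Path-dependent TreeSHAP: canonical single-tree cases, local accuracy,
# exhaustive-Shapley equality and aggregation.

test_that("canonical single-tree cases attribute as expected", {
  # single-leaf (constant) tree: zero attributions, base = constant
  leaf <- list(list(left = -1L, right = -1L, feature = 0L, threshold = 0,
                    value = 0.7, cover = 10))
  x <- matrix(rnorm(6), 2, 3, dimnames = list(NULL, c("a", "b", "c")))
  res <- lonesense:::cpp_forest_shap(x, leaf)
  expect_true(all(res$phi == 0))
  expect_equal(res$base, 0.7)
  # depth-1 stump on feature 2: the whole (output - base) goes to it
  stump <- list(list(left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
                     feature = c(1L, 0L, 0L), threshold = c(0, 0, 0),
                     value = c(0, 0, 1), cover = c(10, 6, 4)))
  xr <- matrix(c(0, 1, 0), 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  r2 <- lonesense:::cpp_forest_shap(xr, stump)
  expect_equal(r2$base, 0.4)
  expect_equal(unname(r2$phi[1, ]), c(0, 1 - 0.4, 0))
  # a feature never used by any tree gets exactly zero
  expect_equal(unname(r2$phi[1, 3]), 0)
})

test_that("tree SHAP equals exhaustive Shapley on small ensembles", {
  set.seed(111)
  n <- 200; p <- 6
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- as.integer(x[, 1] + 0.7 * x[, 2] * x[, 3] + rnorm(n, 0, 0.4) > 0)
  m <- train_model(x, y, hyper = list(num_trees = 5, min_node = 30), seed = 3)
  fo <- forest_structure(m)
  xt <- matrix(rnorm(5 * p), 5, p, dimnames = list(NULL, colnames(x)))
  sh <- tree_shap(m, xt)
  for (i in 1:5) {
    bf <- brute_force_shap(fo, xt[i, ])
    expect_lt(max(abs(bf - sh$values[i, ])), 1e-6)
  }
  # local accuracy against the ranger vote fraction
  expect_lt(max(abs(sh$base_value + rowSums(sh$values) - predict(m, xt))),
            1e-6)
})

test_that("duplicated identical features share attribution symmetrically", {
  set.seed(112)
  n <- 400
  z <- rnorm(n)
  x <- cbind(d1 = z, d2 = z, noise = rnorm(n))
  y <- as.integer(z + rnorm(n, 0, 0.3) > 0)
  tot <- c(d1 = 0, d2 = 0)
  for (s in 1:12) {
    m <- train_model(x, y, hyper = list(num_trees = 120), seed = s)
    xt <- cbind(d1 = (zt <- rnorm(40)), d2 = zt, noise = rnorm(40))
    sh <- tree_shap(m, xt)
    tot <- tot + colMeans(abs(sh$values))[c("d1", "d2")]
  }
  expect_lt(abs(tot["d1"] - tot["d2"]) / mean(tot), 0.25)
})

test_that("importance aggregation ranks and signs sensibly", {
  set.seed(113)
  sp <- small_pipeline()
  ev <- evaluate_all(sp$features, seed = 99, keep_models = TRUE)
  sh <- shap_for_eval(sp$features, ev)
  agg <- aggregate_importance(sh)
  expect_true(all(agg$matrix >= 0))
  expect_equal(nrow(agg$matrix), length(sh))
  # columns are sorted by cross-participant mean importance
  expect_true(!is.unsorted(rev(colMeans(agg$matrix))))
  # every participant satisfies local accuracy on every test record
  for (p in names(sh)) {
    err <- abs(sh[[p]]$base_value + rowSums(sh[[p]]$values) - sh[[p]]$pred)
    expect_lt(max(err), 1e-6)
  }
})
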