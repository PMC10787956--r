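# CART classifier, stratified folds and CV metrics.

test_that("gini follows its closed form", {
  expect_equal(gini(c(10, 0)), 0)
  expect_equal(gini(c(5, 5)), 0.5)
  expect_equal(gini(c(1, 3)), 0.375)
  expect_error(gini(c(0, 0)), "positive sum")
})

test_that("a separable 1-D problem is solved by one midpoint split", {
  fit <- fit_tree(matrix(c(1, 2, 10, 11)), factor(c("a", "a", "b", "b")))
  expect_equal(fit$n_splits, 1L)
  root <- fit$nodes[1, ]
  expect_equal(root$feature, 1L)
  expect_equal(root$threshold, 6)
  pred <- predict(fit, matrix(c(1, 2, 10, 11)))
  expect_equal(as.character(pred), c("a", "a", "b", "b"))
})

test_that("pure labels give a single leaf; XOR needs depth two", {
  leaf <- fit_tree(matrix(rnorm(6)), factor(rep("a", 6)))
  expect_equal(leaf$n_splits, 0L)
  expect_equal(as.character(predict(leaf, matrix(rnorm(3)))),
               rep("a", 3))
  xor_X <- matrix(c(0, 1, 0, 1, 0, 1, 1, 0), ncol = 2)
  xor_y <- factor(c(0, 0, 1, 1))
  fit <- fit_tree(xor_X, xor_y)
  expect_gte(fit$n_splits, 2L)
  expect_equal(as.character(predict(fit, xor_X)), as.character(xor_y))
})

test_that("values equal to a threshold are routed right", {
  fit <- fit_tree(matrix(c(0, 2)), factor(c("lo", "hi")))
  expect_equal(fit$nodes$threshold[1], 1)
  expect_equal(as.character(predict(fit, matrix(1))), "hi")
})

test_that("the first split matches exhaustive search on small datasets", {
  set.seed(29)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    d <- sample(1:2, 1)
    X <- matrix(round(runif(n * d), 2), n, d)
    y01 <- sample(0:1, n, replace = TRUE)
    want <- oracle_first_split(X, y01)
    fit <- fit_tree(X, factor(y01, levels = 0:1))
    if (is.null(want)) {
      expect_equal(fit$n_splits, 0L)
    } else {
      expect_equal(fit$nodes$feature[1], want$feature)
      expect_equal(fit$nodes$threshold[1], want$threshold)
    }
  }
})

test_that("training accuracy is non-decreasing in max_splits", {
  set.seed(30)
  X <- matrix(rnorm(60 * 3), 60)
  y <- factor(sample(c("healthy", "bruxism"), 60, replace = TRUE))
  acc <- vapply(c(1, 3, 10, 30, 100), function(ms) {
    fit <- fit_tree(X, y, max_splits = ms)
    mean(predict(fit, X) == y)
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
  expect_error(fit_tree(matrix(c(1, NA)), factor(c("a", "b"))),
               "non-finite")
})

test_that("stratified folds preserve class balance and partition rows", {
  y <- factor(rep(c("pos", "neg"), c(20, 80)))
  folds <- stratified_kfold(y, k = 5, seed = 3)
  for (f in 1:5) {
    expect_equal(sum(folds == f & y == "pos"), 4L)
    expect_equal(sum(folds == f & y == "neg"), 16L)
  }
  expect_identical(folds, stratified_kfold(y, k = 5, seed = 3))
  expect_false(identical(folds, stratified_kfold(y, k = 5, seed = 4)))
  expect_error(stratified_kfold(factor(c("a", "a", "b")), k = 2),
               "at least k")
})

test_that("metrics follow their confusion-matrix definitions", {
  m <- confusion_metrics(tp = 9, fp = 2, tn = 18, fn = 1)
  expect_equal(unname(m), c(90, 90, 90, 100 * 9 / 11), tolerance = 1e-10)
})

test_that("cross-validation separates disjoint groups and glance is
           consistent", {
  set.seed(31)
  X <- rbind(matrix(rnorm(40 * 2, 0), ncol = 2),
             matrix(rnorm(40 * 2, 6), ncol = 2))
  y <- factor(rep(c("healthy", "bruxism"), each = 40))
  cv <- cv_evaluate(X, y, k = 5, seed = 7)
  expect_gte(cv$metrics[["accuracy"]], 95)
  g <- glance(cv)
  expect_equal(g$accuracy,
               100 * (g$tp + g$tn) / (g$tp + g$tn + g$fp + g$fn))
  expect_equal(sum(cv$confusion), 80)
  expect_equal(nrow(tidy(cv)), 5L)
})

test_that("label-permuted data scores near the chance rate", {
  set.seed(32)
  X <- matrix(rnorm(120 * 4), 120)
  y <- factor(rep(c("healthy", "bruxism"), each = 60))
  cv <- cv_evaluate(X, y[sample(120)], k = 5, seed = 2)
  expect_gt(cv$metrics[["accuracy"]], 30)
  expect_lt(cv$metrics[["accuracy"]], 70)
})

test_that("cv is reproducible for a fixed seed", {
  set.seed(33)
  X <- matrix(rnorm(60 * 3), 60)
  y <- factor(rep(c("healthy", "bruxism"), each = 30))
  g1 <- glance(cv_evaluate(X, y, seed = 11))
  g2 <- glance(cv_evaluate(X, y, seed = 11))
  expect_identical(g1, g2)
})
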