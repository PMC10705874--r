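test_that("the 7:3 split is stratified, exact-sized and seed-stable", {
  tab <- generate_table(synthetic_config(n_samples = 260, n_features = 10, n_informative = 3,
                                         prevalence = 0.49, seed = 2))
  split <- make_split(tab, seed = 5)
  expect_length(split$train_ids, 182)
  expect_length(split$test_ids, 78)
  expect_equal(split$cv_folds, 10L)
  expect_length(intersect(split$train_ids, split$test_ids), 0)
  expect_setequal(c(split$train_ids, split$test_ids), tab$sample_ids)
  train_prev <- mean(tab$outcome[tab$sample_ids %in% split$train_ids])
  expect_lte(abs(train_prev - mean(tab$outcome)), 1 / 182)
  expect_identical(split, make_split(tab, seed = 5))

  small <- generate_table(synthetic_config(n_samples = 100, n_features = 10, n_informative = 3,
                                           prevalence = 0.8, seed = 3))
  split_small <- make_split(small, seed = 1)
  expect_length(split_small$train_ids, 70)
  expect_equal(split_small$cv_folds, 5L)

  # a class too small for the fold count shrinks the folds with a warning
  tiny <- generate_table(synthetic_config(n_samples = 40, n_features = 5, n_informative = 2,
                                          prevalence = 0.1, seed = 4))
  expect_warning(split_tiny <- make_split(tiny, seed = 1), "folds")
  expect_lt(split_tiny$cv_folds, 5L)
})

test_that("z-score normalization fits on training rows only", {
  v_tr <- matrix(c(1, 2, 3, 7, 7, 7), 3, 2,
                 dimnames = list(NULL, c("va", "konst")))
  train <- feature_table(v_tr, c(0, 1, 1))
  v_te <- matrix(c(2, 5, 7, 9), 2, 2,
                 dimnames = list(NULL, c("va", "konst")))
  test <- feature_table(v_te, c(0, 1))
  norm <- zscore_fit_apply(train, test)
  expect_equal(unname(norm$train$values[, "va"]), c(-1, 0, 1)) # sample SD
  expect_equal(unname(norm$train$values[, "konst"]), c(0, 0, 0))
  expect_equal(unname(norm$others[[1]]$values[, "va"]), c(0, 3))
  expect_equal(unname(norm$others[[1]]$values[, "konst"]), c(0, 0))

  # mutating test rows must not change the fitted parameters
  test2 <- feature_table(v_te * 100, c(0, 1))
  norm2 <- zscore_fit_apply(train, test2)
  expect_identical(norm$parameters, norm2$parameters)
  expect_identical(norm$train$values, norm2$train$values)
})

test_that("random-provenance columns are not re-normalized", {
  tab <- make_test_table(n = 30, p = 4, seed = 6)
  inj <- fabricate_random_features(tab, injection_spec(0.5, 1, seed = 2))
  norm <- zscore_fit_apply(inj)
  rand <- feature_names(inj, provenance = "random")
  expect_identical(norm$train$values[, rand], inj$values[, rand])
  real <- feature_names(inj, provenance = "real")
  expect_equal(unname(colMeans(norm$train$values[, real])), rep(0, 4))
})

test_that("oversampling balances classes by duplicating existing rows only", {
  tab <- make_test_table(n = 100, p = 3, seed = 7)
  tab$outcome <- c(rep(1L, 70), rep(0L, 30))
  os <- oversample_training(tab, seed = 3)
  expect_equal(as.vector(table(os$outcome)), c(70, 70))
  extra <- os$values[101:140, , drop = FALSE]
  orig <- apply(tab$values, 1, paste, collapse = ",")
  expect_true(all(apply(extra, 1, paste, collapse = ",") %in% orig))

  balanced <- make_test_table(n = 40, p = 3, seed = 8)
  expect_identical(oversample_training(balanced, seed = 1), balanced)
})

test_that("AUC and threshold metrics follow their definitions", {
  expect_equal(auc_score(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(rep(0.5, 6), rep_len(0:1, 6)), 0.5)
  expect_error(auc_score(c(0.1, 0.9), c(1, 1)), "both classes")

  set.seed(2)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 1)
    expect_equal(auc_score(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("classifiers are deterministic and sensible on separable data", {
  tab <- make_test_table(n = 60, p = 4, signal = 1, effect = 4, seed = 10)
  m1 <- fit_rf(tab, feature_names(tab), seed = 3)
  m2 <- fit_rf(tab, feature_names(tab), seed = 3)
  expect_identical(predict(m1, tab), predict(m2, tab))
  metrics <- evaluate_model(m1, tab)
  expect_gte(metrics$auc, 0.99)
  expect_true(all(unlist(metrics) >= 0 & unlist(metrics) <= 1))

  l1 <- fit_lasso_clf(tab, feature_names(tab), seed = 3, cv_folds = 5)
  l2 <- fit_lasso_clf(tab, feature_names(tab), seed = 3, cv_folds = 5)
  expect_identical(l1$fit$coefficients, l2$fit$coefficients)
  expect_gt(l1$fit$coefficients[["f01"]], 0)

  expect_error(fit_rf(tab, character(0), seed = 1), "empty selection")
  expect_error(fit_lasso_clf(tab, character(0), seed = 1), "empty selection")
})

test_that("an intercept-only LASSO model predicts the training prevalence", {
  tab <- make_test_table(n = 50, p = 3, seed = 20)
  tab$outcome <- c(rep(1L, 30), rep(0L, 20))
  model <- fit_lasso_clf(tab, feature_names(tab), lambda = 1e6)
  expect_equal(predict(model, tab), rep(0.6, 50), tolerance = 1e-6)
})

test_that("pure-noise features give chance-level hold-out AUC", {
  aucs <- vapply(1:20, function(s) {
    tab <- make_test_table(n = 120, p = 5, signal = 0, seed = 300 + s)
    split <- make_split(tab, seed = s)
    train <- subset_table(tab, samples = split$train_ids)
    test <- subset_table(tab, samples = split$test_ids)
    model <- fit_rf(train, feature_names(tab), seed = s, num_trees = 100)
    evaluate_model(model, test)$auc
  }, numeric(1))
  expect_gte(mean(aucs), 0.35)
  expect_lte(mean(aucs), 0.65)
})

test_that("cross-validation averages per-fold validation metrics without leakage", {
  tab <- make_test_table(n = 80, p = 5, signal = 2, effect = 1.5, seed = 15)
  cv1 <- cross_validate(tab, feature_names(tab), "LASSO", cv_folds = 5,
                        seed = 9)
  cv2 <- cross_validate(tab, feature_names(tab), "LASSO", cv_folds = 5,
                        seed = 9)
  expect_identical(cv1, cv2)
  expect_true(all(unlist(cv1) >= 0 & unlist(cv1) <= 1))

  # hand-rolled reference: same folds, same seeds, explicit loop
  foldid <- radinject:::make_stratified_folds(tab$outcome, 5, 9)
  ref <- mean(vapply(1:5, function(f) {
    tr <- subset_table(tab, samples = foldid != f)
    tr <- oversample_training(tr, radinject:::derive_seed(9, "os", f))
    va <- subset_table(tab, samples = foldid == f)
    m <- fit_lasso_clf(tr, feature_names(tab),
                       seed = radinject:::derive_seed(9, "lcv", f),
                       cv_folds = min(5, min(table(tr$outcome))))
    evaluate_model(m, va)$auc
  }, numeric(1)))
  expect_equal(cv1$auc, ref)
})
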