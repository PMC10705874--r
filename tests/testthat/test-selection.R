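test_that("Mann-Whitney exact p-values match enumeration on the canonical examples", {
  # x=(1,2,3) vs y=(4,5,6): U=0, one arrangement per tail of C(6,3)=20
  expect_equal(mann_whitney_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # x=(1,2,3,4) vs y=(5,6,7,8): 2/70
  expect_equal(mann_whitney_p(c(1, 2, 3, 4), c(5, 6, 7, 8)), 2 / 70)
  # symmetric: swapping groups preserves the two-sided p
  expect_equal(mann_whitney_p(c(4, 5, 6), c(1, 2, 3)), 0.1)
  # constant feature: no separation possible
  expect_equal(mann_whitney_p(rep(2, 5), rep(2, 4)), 1)
})

test_that("exact p-values agree with wilcox.test on tie-free data", {
  set.seed(21)
  for (i in 1:25) {
    n1 <- sample(2:8, 1)
    n2 <- sample(2:8, 1)
    x <- rnorm(n1)
    y <- rnorm(n2)
    expect_equal(mann_whitney_p(x, y),
                 suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value),
                 tolerance = 1e-12)
  }
})

test_that("large-sample p-values use the tie-corrected normal approximation", {
  set.seed(4)
  x <- round(rnorm(30), 1) # rounding forces ties
  y <- round(rnorm(25, 0.5), 1)
  expect_equal(mann_whitney_p(x, y),
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("the filter keeps separated features and drops flat or alpha-capped ones", {
  tab <- make_test_table(n = 60, p = 8, signal = 2, effect = 2, seed = 5)
  kept <- mann_whitney_filter(tab, alpha = 0.05)
  expect_true(all(c("f01", "f02") %in% kept))
  expect_setequal(mann_whitney_filter(tab, alpha = 1), feature_names(tab))
  expect_length(mann_whitney_filter(tab, alpha = 1e-300), 0)

  v <- cbind(tab$values, flat = 1)
  tab2 <- feature_table(v, tab$outcome)
  expect_false("flat" %in% mann_whitney_filter(tab2, alpha = 0.9999))
})

test_that("MRMR matches a brute-force greedy oracle", {
  # k=1 reduces to the max-F feature
  tab <- make_test_table(n = 50, p = 6, signal = 1, effect = 3, seed = 9)
  one <- select_mrmr(tab, feature_names(tab), 1)
  expect_equal(one$selected, "f01")

  for (s in 1:10) {
    tab <- make_test_table(n = 40, p = 6, signal = 2, seed = 100 + s)
    got <- select_mrmr(tab, feature_names(tab), 4)$selected
    want <- oracle_mrmr(tab$values, tab$outcome, feature_names(tab), 4)
    expect_equal(got, want)
  }
})

test_that("MRMR penalizes an exact duplicate of the first pick", {
  # a1 and a2 are identical; b has exactly the same relevance (a within-class
  # permutation of a1, so identical group means and variances) but |cor| < 1
  # with a1. After a1 is picked (lexicographic tie-break among equal F),
  # a2's redundancy penalty is maximal, so b must rank ahead of it.
  set.seed(3)
  n <- 60
  outcome <- rep_len(0:1, n)
  a <- rnorm(n) + 2 * outcome
  b <- a
  for (cls in 0:1) {
    idx <- which(outcome == cls)
    b[idx] <- a[idx][sample.int(length(idx))]
  }
  v <- cbind(a1 = a, a2 = a, b = b)
  tab <- feature_table(v, outcome)
  res <- select_mrmr(tab, colnames(v), 3)
  expect_equal(res$selected[1], "a1")
  expect_equal(res$selected[2], "b")
  expect_equal(res$selected[3], "a2")
})

test_that("RFE follows the 10%-drop schedule and recovers a planted signal", {
  tab <- make_test_table(n = 60, p = 30, seed = 6)
  res <- select_rfe(tab, feature_names(tab), 30, seed = 1)
  expect_setequal(res$selected, feature_names(tab)) # k >= |candidates|: identity

  # schedule for 100 candidates: 100 -> 90 -> 81 -> ... strictly decreasing
  tab100 <- make_test_table(n = 40, p = 100, seed = 17)
  res100 <- select_rfe(tab100, feature_names(tab100), 20, seed = 2,
                       num_trees = 50)
  sched <- attr(res100, "schedule")
  expect_equal(sched[1:3], c(100, 90, 81))
  expect_true(all(diff(sched) < 0))
  expect_equal(tail(sched, 1), 20)
  expect_length(res100$selected, 20)

  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 60
    outcome <- rep_len(0:1, n)
    v <- matrix(rnorm(n * 8), n, 8,
                dimnames = list(NULL, sprintf("f%02d", 1:8)))
    v[, "f05"] <- outcome + rnorm(n, sd = 0.05)
    tab <- feature_table(v, outcome)
    select_rfe(tab, colnames(v), 1, seed = s)$selected == "f05"
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("LASSO selection caps at k by coefficient magnitude and respects direction", {
  tab <- make_test_table(n = 80, p = 10, signal = 6, effect = 1.5, seed = 12)
  res <- select_lasso(tab, feature_names(tab), 3, seed = 1, cv_folds = 5)
  expect_lte(length(res$selected), 3)
  full <- select_lasso(tab, feature_names(tab), 10, seed = 1, cv_folds = 5)
  top3 <- names(sort(full$scores, decreasing = TRUE))[1:3]
  expect_setequal(res$selected, top3)

  # a fixed huge penalty shrinks everything: empty selection with a warning
  expect_warning(
    empty <- select_lasso(tab, feature_names(tab), 5, lambda = 1e6),
    "empty")
  expect_length(empty$selected, 0)

  # single separated feature: selected, and the model coefficient's sign
  # matches the direction of class separation
  tab1 <- make_test_table(n = 80, p = 1, signal = 1, effect = 2, seed = 4)
  res1 <- select_lasso(tab1, "f01", 1, seed = 2, cv_folds = 5)
  expect_equal(res1$selected, "f01")
  model <- fit_lasso_clf(tab1, "f01", seed = 2, cv_folds = 5)
  expect_gt(model$fit$coefficients[["f01"]], 0)
})

test_that("all selectors respect the threshold and the filter funnel", {
  tab <- generate_table(synthetic_config(n_samples = 120, n_features = 30,
                                         n_informative = 6, seed = 31))
  tab <- fabricate_random_features(tab, injection_spec(0.5, 1, seed = 8))
  survivors <- mann_whitney_filter(tab)
  for (fn in list(select_mrmr,
                  function(t, c, k) select_rfe(t, c, k, seed = 2),
                  function(t, c, k) select_lasso(t, c, k, seed = 2,
                                                 cv_folds = 5))) {
    res <- fn(tab, survivors, 5)
    expect_lte(length(res$selected), 5)
    expect_true(all(res$selected %in% survivors))
    expect_true(all(survivors %in% feature_names(tab)))
  }
})

test_that("selectors enrich planted informative features over noise", {
  enrich <- vapply(1:8, function(s) {
    tab <- generate_table(synthetic_config(
      n_samples = 150, n_features = 24, n_informative = 6, effect_size = 1,
      seed = 400 + s))
    survivors <- mann_whitney_filter(tab)
    sel <- select_mrmr(tab, survivors, 6)$selected
    mean(tab$informative_truth[sel])
  }, numeric(1))
  # random expectation would be 6/24 = 0.25; require >= 2x enrichment
  expect_gte(mean(enrich), 0.5)
})

test_that("selection results serialize to JSON", {
  tab <- make_test_table(n = 40, p = 6, signal = 2, seed = 2)
  res <- select_mrmr(tab, feature_names(tab), 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_selection_result(res, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$selector, "MRMR")
  expect_equal(unlist(back$selected), res$selected)
  expect_equal(back$n_filter_survivors, 6)
})
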