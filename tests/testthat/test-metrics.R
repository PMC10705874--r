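test_that("contamination ratio counts random-provenance picks", {
  prov <- setNames(rep(c("real", "random"), c(60, 40)),
                   c(sprintf("feat_%03d", 1:60), sprintf("random_%03d", 1:40)))
  sel20 <- c(sprintf("feat_%03d", 1:9), sprintf("random_%03d", 1:11))
  expect_equal(contamination_ratio(sel20, prov), 0.55) # 11 of 20
  sel50 <- c(sprintf("feat_%03d", 1:32), sprintf("random_%03d", 1:18))
  expect_equal(contamination_ratio(sel50, prov), 0.36) # 18 of 50
  expect_equal(contamination_ratio(sprintf("feat_%03d", 1:5), prov), 0)
  expect_error(contamination_ratio(character(0), prov), "empty")
  expect_error(contamination_ratio("unknown", prov), "provenance")
})

test_that("pairwise and multi-set Jaccard follow the set definitions", {
  expect_equal(jsc_pair(c("A", "B"), c("A", "B")), 1)
  expect_equal(jsc_pair(c("A", "B"), c("C", "D")), 0)
  expect_equal(jsc_pair(c("A", "B"), c("B", "C")), 1 / 3)
  expect_error(jsc_pair(character(0), character(0)), "empty")

  expect_equal(jsc_multiset(rep(list(c("X", "Y")), 20)), 1)
  expect_equal(jsc_multiset(list(c("A", "B"), c("B", "C"), c("B", "D"))),
               0.25)
  expect_error(jsc_multiset(list(character(0), character(0))), "empty")
})

test_that("multi-set Jaccard never exceeds the worst pairwise value", {
  set.seed(5)
  for (i in 1:50) {
    sets <- lapply(1:4, function(j) sample(letters, sample(3:10, 1)))
    multi <- jsc_multiset(sets)
    pairs <- combn(4, 2)
    worst <- min(apply(pairs, 2, function(ix)
      jsc_pair(sets[[ix[1]]], sets[[ix[2]]])))
    expect_lte(multi, worst + 1e-12)
    expect_equal(multi, oracle_jsc_multi(sets))
  }
})

test_that("selection stability drops injected features before scoring", {
  prov <- c(a = "real", b = "real", c = "real", r1 = "random", r2 = "random")
  sets <- list(c("a", "b", "r1"), c("a", "b", "r2"), c("a", "c"))
  expect_equal(selection_stability(sets, prov), 1 / 3) # {a} over {a,b,c}
  expect_equal(selection_stability(sets, prov, include_random = TRUE),
               1 / 5)
  only_random <- list(c("r1"), c("r2"))
  expect_true(is.na(selection_stability(only_random, prov)))
})

test_that("permutation importance isolates the features a model uses", {
  set.seed(31)
  n <- 150
  outcome <- rep_len(0:1, n)
  v <- cbind(signal = outcome + rnorm(n, sd = 0.1), noise = rnorm(n))
  colnames(v) <- c("signal", "noise")
  tab <- feature_table(v, outcome)
  model <- fit_rf(tab, c("signal", "noise"), seed = 2)
  raw <- rf_permutation_importance(model, tab, n_permutations = 100,
                                   seed = 3)
  expect_lt(raw[["noise"]], 0.02)
  expect_gt(raw[["signal"]], 0.2)
  pct <- normalize_importance(raw)
  expect_gt(pct[["signal"]], 95)

  # doubling the permutation count reduces Monte-Carlo variance
  est <- function(np) vapply(1:20, function(s)
    rf_permutation_importance(model, tab, n_permutations = np,
                              seed = s)[["signal"]], numeric(1))
  expect_lt(var(est(8)), var(est(2)))
})

test_that("LASSO importance is the absolute coefficient magnitude", {
  model <- structure(
    list(kind = "LASSO",
         fit = list(coefficients = c(fa = 2, fb = -2, fc = 0),
                    intercept = 0.7),
         features = c("fa", "fb", "fc")),
    class = "radinject_model")
  imp <- lasso_importance(model)
  expect_equal(imp, c(fa = 2, fb = 2, fc = 0))
  model$fit$coefficients[["fa"]] <- 4
  expect_equal(lasso_importance(model)[["fa"]], 4)
})

test_that("importance normalization produces shares summing to 100", {
  expect_equal(unname(normalize_importance(c(a = 1, b = 1, c = 2))),
               c(25, 25, 50))
  expect_equal(unname(normalize_importance(c(solo = 7))), 100)
  set.seed(9)
  for (i in 1:20) {
    raw <- setNames(runif(sample(2:15, 1)), NULL)
    names(raw) <- paste0("f", seq_along(raw))
    pct <- normalize_importance(raw)
    expect_equal(sum(pct), 100, tolerance = 1e-9)
    # permutation-invariance to feature order
    perm <- sample(seq_along(raw))
    expect_equal(normalize_importance(raw[perm]), pct[perm])
  }
  expect_warning(zero <- normalize_importance(c(a = 0, b = 0)), "zero")
  expect_equal(unname(zero), c(0, 0))
  expect_equal(unname(normalize_importance(c(a = 1, b = 4), "max100")),
               c(25, 100))
})

test_that("importance aggregation follows the top-10 conventions", {
  prov <- c(fa = "real", fb = "real", random_01 = "random",
            random_02 = "random")
  # a single evaluation aggregates to itself
  one <- list(c(fa = 60, fb = 30, random_01 = 10))
  agg1 <- aggregate_importance(one, prov)
  expect_equal(agg1$top10_real, c(fa = 60, fb = 30))
  expect_equal(agg1$top10_random_mean[1:2], c(10, 0))
  expect_equal(agg1$total_random_contribution, 10)

  # absent features count as 0 in the per-feature mean
  two <- list(c(fa = 50, fb = 50), c(fa = 100))
  agg2 <- aggregate_importance(two, prov)
  expect_equal(agg2$top10_real, c(fa = 75, fb = 25))
  expect_equal(agg2$top10_random_mean, rep(0, 10))
  expect_equal(agg2$total_random_contribution, 0)
})

test_that("two-group ANOVA reduces to the squared pooled t statistic", {
  set.seed(12)
  for (i in 1:10) {
    a <- rnorm(8)
    b <- rnorm(10, mean = 0.5)
    res <- anova_bonferroni(c(a, b), rep(c("g1", "g2"), c(8, 10)))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("Bonferroni adjustment caps at 1 and flat data give p = 1", {
  res <- anova_bonferroni(c(1, 2, 1, 2, 1, 2), rep(c("a", "b"), 3),
                          families = 50)
  expect_lte(res$p_adjusted, 1)
  flat <- anova_bonferroni(rep(3, 8), rep(c("a", "b"), 4))
  expect_equal(flat$f, 0)
  expect_equal(flat$p_adjusted, 1)
  same_mean <- anova_bonferroni(c(1, 2, 1, 2), rep(c("a", "b"), each = 2),
                                families = 2)
  expect_false(same_mean$significant)
})
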