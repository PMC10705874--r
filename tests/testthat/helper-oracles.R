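# Independent oracles and fixture builders used across the suite. Each
# oracle deliberately takes a different computational route than the
# package implementation it checks.

# Exact two-sided Mann-Whitney p-value by brute-force enumeration: assigns
# every combination of the pooled observed values to group 1 and counts
# pairwise wins (ties worth 1/2). Independent of the package's rank-based
# exact path.
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(a, b) {
    u <- 0
    for (ai in a) for (bi in b) {
      u <- u + (ai > bi) + 0.5 * (ai == bi)
    }
    u
  }
  u_obs <- u_of(x, y)
  combos <- utils::combn(length(pooled), n1)
  u_null <- apply(combos, 2, function(idx) {
    u_of(pooled[idx], pooled[-idx])
  })
  eps <- 1e-9
  min(1, 2 * min(mean(u_null <= u_obs + eps), mean(u_null >= u_obs - eps)))
}

# AUC by explicit pairwise concordance counting.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Multi-set Jaccard via incremental set folding (package uses Reduce over
# the whole list at once; this walks pairwise and tracks both sets by hand).
oracle_jsc_multi <- function(sets) {
  inter <- sets[[1]]
  uni <- sets[[1]]
  for (s in sets[-1]) {
    inter <- inter[inter %in% s]
    uni <- c(uni, s[!(s %in% uni)])
  }
  length(unique(inter)) / length(unique(uni))
}

# Brute-force greedy MRMR: at every step scores every remaining candidate
# from scratch, with relevance computed through R's linear-model ANOVA
# rather than the package's closed-form F.
oracle_mrmr <- function(values, outcome, candidates, k) {
  candidates <- sort(candidates)
  keep <- candidates[apply(values[, candidates, drop = FALSE], 2,
                           stats::var) > 0]
  relev <- vapply(keep, function(f) {
    fit <- stats::aov(values[, f] ~ factor(outcome))
    summary(fit)[[1]][["F value"]][1]
  }, numeric(1))
  selected <- character(0)
  for (step in seq_len(min(k, length(keep)))) {
    remaining <- setdiff(keep, selected)
    crit <- vapply(remaining, function(f) {
      red <- if (length(selected) == 0) 0 else
        mean(abs(stats::cor(values[, f], values[, selected, drop = FALSE])))
      relev[[f]] - red
    }, numeric(1))
    best <- remaining[crit == max(crit)]
    selected <- c(selected, sort(best)[1])
  }
  selected
}

# Small random table: independent Gaussian features, optional signal in
# the first `signal` features.
make_test_table <- function(n = 40, p = 6, signal = 0, effect = 1.5,
                            seed = 1) {
  set.seed(seed)
  outcome <- rep_len(c(0L, 1L), n)
  values <- matrix(rnorm(n * p), n, p,
                   dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  if (signal > 0) {
    values[outcome == 1L, seq_len(signal)] <-
      values[outcome == 1L, seq_len(signal)] + effect
  }
  feature_table(values, outcome)
}
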