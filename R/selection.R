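#' Two-sided Mann-Whitney U p-value
#'
#' Compares a continuous feature between the two outcome groups. When both
#' group sizes are at most 8 the exact permutation null of the U statistic is
#' used (enumerating all assignments of the pooled mid-ranks to one group, so
#' ties are handled exactly); otherwise the normal approximation with tie
#' correction and continuity correction is used. The two-sided p-value is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param x Numeric values for group 1.
#' @param y Numeric values for group 2.
#' @return Two-sided p-value. A feature constant across all samples gives
#'   p = 1.
#' @export
mann_whitney_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) return(1)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (max(n1, n2) <= 8L) {
    combos <- utils::combn(n1 + n2, n1)
    u_null <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    lower <- mean(u_null <= u + eps)
    upper <- mean(u_null >= u - eps)
    return(min(1, 2 * min(lower, upper)))
  }
  n <- n1 + n2
  ties <- table(pooled)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  mu <- n1 * n2 / 2
  z <- u - mu
  # continuity correction toward the mean, as in the classical two-sided test
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Filter features by Mann-Whitney U test
#'
#' Univariate pre-filter applied before feature selection: keeps features
#' whose two-sided Mann-Whitney p-value comparing the two outcome groups is
#' below `alpha`. Constant features get p = 1 and are dropped silently.
#'
#' @param table A [feature_table()] (typically the training split).
#' @param alpha Significance threshold (default 0.05).
#' @return Character vector of surviving feature names, in table column order.
#' @export
mann_whitney_filter <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  pos <- table$outcome == 1L
  keep <- vapply(colnames(table$values), function(nm) {
    mann_whitney_p(table$values[pos, nm], table$values[!pos, nm]) < alpha
  }, logical(1))
  colnames(table$values)[keep]
}

new_selection_result <- function(selector, max_threshold, filter_survivors,
                                 selected, scores) {
  structure(
    list(selector = selector, max_threshold = as.integer(max_threshold),
         filter_survivors = filter_survivors, selected = selected,
         scores = scores),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s (max %d): %d selected of %d survivors\n",
              x$selector, x$max_threshold, length(x$selected),
              length(x$filter_survivors)))
  invisible(x)
}

#' Serialize a selection result to JSON
#' @param result A `selection_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_result <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  jsonlite::write_json(
    list(selector = result$selector, max_threshold = result$max_threshold,
         n_filter_survivors = length(result$filter_survivors),
         selected = result$selected, scores = as.list(result$scores)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# one-way ANOVA F statistic of a feature against the binary outcome;
# 0 for a feature without within- or between-group variance
f_statistic <- function(x, outcome) {
  g1 <- x[outcome == 1L]
  g0 <- x[outcome == 0L]
  n1 <- length(g1); n0 <- length(g0)
  gm <- mean(x)
  ssb <- n1 * (mean(g1) - gm)^2 + n0 * (mean(g0) - gm)^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g0 - mean(g0))^2)
  if (ssw <= 0) {
    if (ssb <= 0) return(0)
    return(Inf)
  }
  (ssb / 1) / (ssw / (n1 + n0 - 2))
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy forward MRMR with the difference criterion on continuous features:
#' the first pick maximizes relevance (the one-way ANOVA F statistic of
#' feature vs outcome); each subsequent pick maximizes relevance minus the
#' mean absolute Pearson correlation with the already-selected set. Ties are
#' broken by lexicographic feature name. Zero-variance candidates are
#' excluded up front (their relevance is 0 and their correlation undefined).
#'
#' @param table A [feature_table()] (training split).
#' @param candidates Character vector of candidate feature names (e.g. the
#'   output of [mann_whitney_filter()]).
#' @param k Maximum number of features to select.
#' @return A `selection_result` with `selected` ordered by selection step and
#'   `scores` holding each pick's criterion value at its step.
#' @export
select_mrmr <- function(table, candidates, k) {
  stopifnot(inherits(table, "feature_table"), length(candidates) >= 1, k >= 1)
  candidates <- sort(intersect(colnames(table$values), candidates))
  x <- table$values[, candidates, drop = FALSE]
  variances <- apply(x, 2, stats::var)
  usable <- candidates[variances > 0]
  if (length(usable) == 0L) {
    return(new_selection_result("MRMR", k, candidates, character(0), numeric(0)))
  }
  x <- x[, usable, drop = FALSE]
  relevance <- apply(x, 2, f_statistic, outcome = table$outcome)
  cors <- abs(stats::cor(x))
  k_eff <- min(k, length(usable))
  selected <- character(0)
  scores <- numeric(0)
  remaining <- usable
  for (step in seq_len(k_eff)) {
    if (length(selected) == 0L) {
      crit <- relevance[remaining]
    } else {
      redundancy <- colMeans(cors[selected, remaining, drop = FALSE])
      crit <- relevance[remaining] - redundancy
    }
    # which.max on a sorted name vector gives the lexicographic tie-break
    best <- remaining[which.max(crit)]
    selected <- c(selected, best)
    scores <- c(scores, stats::setNames(max(crit), best))
    remaining <- setdiff(remaining, best)
  }
  new_selection_result("MRMR", k, candidates, selected, scores)
}

#' Recursive feature elimination with a random-forest backing estimator
#'
#' Repeatedly fits a random forest (500 trees, impurity importance) on the
#' current candidate set and drops the lowest-importance 10% of features (at
#' least one) per iteration until at most `k` remain. Survivors are ranked by
#' the final model's importance. Importance ties are broken by lexicographic
#' feature name.
#'
#' @param table A [feature_table()] (training split).
#' @param candidates Character vector of candidate feature names.
#' @param k Maximum number of features to keep. `k >= length(candidates)`
#'   returns all candidates without any elimination round.
#' @param seed Integer seed (per-iteration forests get derived seeds).
#' @param num_trees Number of trees per forest (default 500).
#' @return A `selection_result`; `scores` are final-model importances and
#'   attribute `"schedule"` records the candidate-set size at each
#'   iteration.
#' @export
select_rfe <- function(table, candidates, k, seed = 1L, num_trees = 500L) {
  stopifnot(inherits(table, "feature_table"), length(candidates) >= 1, k >= 1)
  candidates <- sort(intersect(colnames(table$values), candidates))
  current <- candidates
  y <- factor(table$outcome, levels = c(0L, 1L))
  iter <- 0L
  rf_importance <- function(feats, s) {
    fit <- ranger::ranger(
      x = as.data.frame(table$values[, feats, drop = FALSE]),
      y = y, num.trees = num_trees, importance = "impurity",
      seed = s, num.threads = 1)
    imp <- fit$variable.importance[feats]
    # lexicographic tie-break: order by (-importance, name)
    imp[order(-imp, names(imp))]
  }
  schedule <- length(current)
  while (length(current) > k) {
    iter <- iter + 1L
    imp <- rf_importance(current, derive_seed(seed, "rfe", iter))
    n_drop <- max(1L, floor(0.1 * length(current)))
    n_drop <- min(n_drop, length(current) - k)
    current <- names(imp)[seq_len(length(imp) - n_drop)]
    schedule <- c(schedule, length(current))
  }
  imp <- rf_importance(current, derive_seed(seed, "rfe", iter + 1L))
  out <- new_selection_result("RFE", k, candidates, names(imp), imp)
  attr(out, "schedule") <- schedule
  out
}

#' LASSO feature selection
#'
#' Fits an L1-penalized logistic regression over a log-spaced penalty grid
#' with the penalty chosen by internal stratified cross-validation on the
#' binomial deviance. Features with non-zero coefficients at the chosen
#' penalty are selected; if more than `k` are non-zero, the `k` largest by
#' absolute coefficient are kept. Fewer than `k` may be returned — the
#' threshold is a maximum, not a quota.
#'
#' @param table A [feature_table()] (training split).
#' @param candidates Character vector of candidate feature names.
#' @param k Maximum number of features.
#' @param seed Integer seed controlling the CV fold assignment.
#' @param cv_folds Folds for the internal penalty CV (default 10).
#' @param lambda Optional fixed penalty value, bypassing the internal CV
#'   (used for degenerate-penalty analyses).
#' @return A `selection_result`; `scores` are absolute coefficients. An
#'   empty selection (every coefficient shrunk to zero) is returned with a
#'   warning; downstream model fitting refuses empty selections.
#' @export
select_lasso <- function(table, candidates, k, seed = 1L, cv_folds = 10L,
                         lambda = NULL) {
  stopifnot(inherits(table, "feature_table"), length(candidates) >= 1, k >= 1)
  candidates <- sort(intersect(colnames(table$values), candidates))
  x <- table$values[, candidates, drop = FALSE]
  y <- table$outcome
  fit <- lasso_fit(x, y, seed = seed, cv_folds = cv_folds, lambda = lambda)
  coefs <- fit$coefficients
  nz <- coefs[coefs != 0]
  if (length(nz) == 0L) {
    warning("LASSO shrank every coefficient to zero; empty selection",
            call. = FALSE)
    return(new_selection_result("LASSO", k, candidates, character(0),
                                numeric(0)))
  }
  scores <- abs(nz)
  ord <- order(-scores, names(scores))
  selected <- names(scores)[ord]
  if (length(selected) > k) selected <- selected[seq_len(k)]
  new_selection_result("LASSO", k, candidates, selected, scores[selected])
}

# Shared L1-penalized logistic fit used by both the selector and the
# classifier. Stratified fold ids are built from the seed so the chosen
# penalty is reproducible. glmnet needs >= 2 columns; a constant dummy is
# appended for single-feature fits and stripped from the result.
lasso_fit <- function(x, y, seed = 1L, cv_folds = 10L, lambda = NULL,
                      nlambda = 100L) {
  feats <- colnames(x)
  padded <- FALSE
  if (ncol(x) == 1L) {
    x <- cbind(x, .pad_ = 0)
    padded <- TRUE
  }
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(x, y, family = "binomial", lambda = lambda,
                          standardize = TRUE)
    beta <- as.numeric(stats::coef(fit, s = lambda))
  } else {
    cv_folds <- min(cv_folds, min(table(y)))
    foldid <- make_stratified_folds(y, cv_folds, seed)
    cv <- glmnet::cv.glmnet(x, y, family = "binomial",
                            type.measure = "deviance", foldid = foldid,
                            nlambda = nlambda, standardize = TRUE)
    fit <- cv$glmnet.fit
    lambda <- cv$lambda.min
    beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
  }
  names(beta) <- c("(Intercept)", colnames(x))
  if (padded) beta <- beta[names(beta) != ".pad_"]
  list(fit = fit, lambda = lambda,
       intercept = beta[["(Intercept)"]],
       coefficients = beta[feats])
}
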