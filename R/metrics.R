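#' Contamination ratio of a selection
#'
#' Fraction of the selected features that are injected random features.
#'
#' @param selected Character vector of selected feature names (or a
#'   `selection_result`).
#' @param provenance Named character vector mapping feature name ->
#'   `"real"`/`"random"` (e.g. a table's `$provenance`).
#' @return Fraction in `[0, 1]`. An empty selection is an error: a ratio of
#'   zero would silently conflate "nothing selected" with "nothing random".
#' @export
contamination_ratio <- function(selected, provenance) {
  if (inherits(selected, "selection_result")) selected <- selected$selected
  if (length(selected) == 0L) {
    stop("contamination ratio undefined for an empty selection", call. = FALSE)
  }
  if (!all(selected %in% names(provenance))) {
    stop("every selected feature needs a provenance flag", call. = FALSE)
  }
  mean(provenance[selected] == "random")
}

#' Jaccard similarity of two feature sets
#'
#' `|A intersect B| / |A union B|`; 1 means the exact same features were
#' selected, 0 means no feature in common.
#'
#' @param a,b Character vectors (treated as sets).
#' @return Similarity in `[0, 1]`; both sets empty is an error (0/0).
#' @export
jsc_pair <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0L) stop("JSC undefined for two empty sets", call. = FALSE)
  length(intersect(a, b)) / length(u)
}

#' Multi-set Jaccard similarity
#'
#' The intersection of all sets over their union — the stability of a
#' selector across all repetitions at one injection level. Callers assessing
#' the stability of the *radiomics* selection should drop random-provenance
#' features from each set first (see [selection_stability()]).
#'
#' @param sets List of at least two character vectors.
#' @return Similarity in `[0, 1]`; an empty union is an error.
#' @export
jsc_multiset <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2)
  sets <- lapply(sets, unique)
  u <- Reduce(union, sets)
  if (length(u) == 0L) stop("JSC undefined: union of sets is empty",
                            call. = FALSE)
  length(Reduce(intersect, sets)) / length(u)
}

#' Selection stability across repetitions
#'
#' Multi-set Jaccard of the selected feature sets across repetitions at one
#' injection level. By default injected random features are removed from
#' every set first, so the statistic measures the consistency of the
#' *radiomics* features selected; set `include_random = TRUE` for a
#' sensitivity analysis on the raw sets.
#'
#' @param results List of `selection_result`s (one per repetition).
#' @param provenance Named provenance vector covering every selected name.
#' @param include_random Keep injected features in the sets (default FALSE).
#' @return Multi-set Jaccard in `[0, 1]`, or `NA` if the union is empty
#'   after filtering.
#' @export
selection_stability <- function(results, provenance, include_random = FALSE) {
  sets <- lapply(results, function(r) {
    s <- if (inherits(r, "selection_result")) r$selected else r
    if (!include_random) s <- s[provenance[s] != "random"]
    s
  })
  if (length(Reduce(union, sets)) == 0L) return(NA_real_)
  jsc_multiset(sets)
}

#' Permutation feature importance for a random-forest model
#'
#' For each feature, the model's accuracy drop when that column is randomly
#' permuted (holding the others fixed), averaged over `n_permutations`
#' independent permutations. Negative raw values — permuting a useless
#' feature can improve accuracy by chance — are floored at 0 so the
#' subsequent percentage normalization is well defined.
#'
#' @param model A fitted `radinject_model` of kind `"RF"`.
#' @param table The [feature_table()] to permute and score (the training
#'   split, matching how importance is usually reported for these models).
#' @param n_permutations Permutations per feature (default 10).
#' @param seed Integer seed.
#' @param cutoff Probability cutoff for accuracy (default 0.5).
#' @return Named numeric vector of raw importances (mean decrease in
#'   accuracy), one per model feature.
#' @export
rf_permutation_importance <- function(model, table, n_permutations = 10L,
                                      seed = 1L, cutoff = 0.5) {
  stopifnot(inherits(model, "radinject_model"))
  y <- table$outcome
  n <- length(y)
  p <- length(model$features)
  base_acc <- mean(as.integer(predict(model, table) >= cutoff) == y)
  x0 <- table$values[, model$features, drop = FALSE]
  # stack every (feature, permutation) copy so the forest is queried once
  stacked <- x0[rep(seq_len(n), p * n_permutations), , drop = FALSE]
  block <- 0L
  for (col in seq_len(p)) {
    perms <- with_seed(derive_seed(seed, "permimp", model$features[col]), {
      replicate(n_permutations, sample.int(n), simplify = FALSE)
    })
    for (b in seq_len(n_permutations)) {
      rows <- block * n + seq_len(n)
      stacked[rows, col] <- x0[perms[[b]], col]
      block <- block + 1L
    }
  }
  pr <- predict(model, list(values = stacked))
  hit <- as.integer(pr >= cutoff) == rep(y, p * n_permutations)
  perm_acc <- colMeans(matrix(hit, nrow = n))
  imp <- base_acc - colMeans(matrix(perm_acc, nrow = n_permutations))
  names(imp) <- model$features
  pmax(imp, 0)
}

#' Coefficient-magnitude importance for a LASSO model
#'
#' Raw importance is the absolute value of each fitted coefficient
#' (intercept excluded).
#'
#' @param model A fitted `radinject_model` of kind `"LASSO"`.
#' @return Named numeric vector of `|coefficient|` per feature.
#' @export
lasso_importance <- function(model) {
  stopifnot(inherits(model, "radinject_model"), model$kind == "LASSO")
  abs(model$fit$coefficients)
}

#' Scale raw importances to percentages
#'
#' With the default `"share"` convention each value becomes its share of
#' the total, on a 0-100 scale, so the output sums to 100; this is what
#' makes per-feature "contribution" percentages addable across features
#' and is the convention used throughout the package. `"max100"` instead
#' rescales so the largest value is 100 (the convention of some
#' variable-importance reports), provided for sensitivity analyses.
#'
#' @param raw Named non-negative numeric vector.
#' @param method `"share"` (default) or `"max100"`.
#' @return Named vector of percentages (summing to 100 under `"share"`);
#'   an all-zero input is returned as all zeros with a warning.
#' @export
normalize_importance <- function(raw, method = c("share", "max100")) {
  method <- match.arg(method)
  stopifnot(all(raw >= 0))
  denom <- if (method == "share") sum(raw) else max(raw)
  if (denom == 0) {
    warning("all raw importances are zero; returning zeros", call. = FALSE)
    return(raw)
  }
  raw * 100 / denom
}

#' Model importance as percentages
#'
#' Convenience wrapper: permutation importance for RF models (on the given
#' table), coefficient magnitude for LASSO models, normalized to a 0-100
#' percentage scale.
#'
#' @inheritParams rf_permutation_importance
#' @return Named percentage vector summing to 100 (or all zeros).
#' @export
model_importance <- function(model, table, n_permutations = 10L, seed = 1L) {
  raw <- if (model$kind == "RF") {
    rf_permutation_importance(model, table, n_permutations, seed)
  } else {
    lasso_importance(model)
  }
  suppressWarnings(normalize_importance(raw))
}

#' Aggregate feature importances at one injection level
#'
#' Mirrors the reporting convention for top features: for the real
#' (radiomics) features, each feature's importance is averaged across all
#' evaluations at the level (a feature absent from an evaluation's model
#' contributes 0) and the ten largest means are kept; for random features,
#' each evaluation contributes its ten largest random-feature importances
#' (padded with 0), which are averaged position-wise; the total random
#' contribution is the mean over evaluations of the summed random-feature
#' percentages.
#'
#' @param importances List, one element per evaluation at the level, each a
#'   named percentage vector (as from [model_importance()]).
#' @param provenance Named provenance vector covering every feature name.
#' @return List with `top10_real` (named, sorted descending),
#'   `top10_random_mean` (length 10, sorted descending), and
#'   `total_random_contribution`.
#' @export
aggregate_importance <- function(importances, provenance) {
  stopifnot(length(importances) >= 1)
  all_real <- unique(unlist(lapply(importances, function(im) {
    names(im)[provenance[names(im)] == "real"]
  })))
  real_mean <- vapply(all_real, function(f) {
    mean(vapply(importances, function(im) {
      if (f %in% names(im)) im[[f]] else 0
    }, numeric(1)))
  }, numeric(1))
  top10_real <- utils::head(sort(real_mean, decreasing = TRUE), 10L)

  rand_top <- vapply(importances, function(im) {
    rv <- sort(im[provenance[names(im)] == "random"], decreasing = TRUE)
    out <- numeric(10L)
    out[seq_len(min(10L, length(rv)))] <- rv[seq_len(min(10L, length(rv)))]
    out
  }, numeric(10L))
  rand_total <- vapply(importances, function(im) {
    sum(im[provenance[names(im)] == "random"])
  }, numeric(1))

  list(top10_real = top10_real,
       top10_random_mean = rowMeans(matrix(rand_top, nrow = 10L)),
       total_random_contribution = mean(rand_total))
}

#' One-way ANOVA across groups with Bonferroni correction
#'
#' For each model combination, tests whether a metric differs across
#' injection levels with a one-way ANOVA F-test, then Bonferroni-adjusts the
#' p-value for the number of comparisons in the family.
#'
#' @param values Numeric metric values.
#' @param groups Factor (or coercible) grouping, at least two groups with at
#'   least two observations each.
#' @param families Number of comparisons in the Bonferroni family
#'   (default 1).
#' @return List: `f`, `p`, `p_adjusted` (capped at 1), and `significant`
#'   (adjusted p < 0.05). Groups with identical means and zero variance
#'   give F = 0, p = 1.
#' @export
anova_bonferroni <- function(values, groups, families = 1L) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2, all(table(groups) >= 2),
            families >= 1)
  if (stats::var(values) == 0) {
    return(list(f = 0, p = 1, p_adjusted = 1, significant = FALSE))
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  if (is.na(f)) { # no residual df or zero residual variance
    f <- if (all(tab[["Mean Sq"]] == 0)) 0 else Inf
    p <- if (f == 0) 1 else 0
  }
  p_adj <- min(1, p * families)
  list(f = f, p = p, p_adjusted = p_adj, significant = p_adj < 0.05)
}
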