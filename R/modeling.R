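#' Stratified 70/30 train / hold-out split
#'
#' Splits a table into a training set of exactly `round(0.7 * n)` samples and
#' a hold-out test set, stratified by outcome: the training set gets
#' `round(0.7 * n_positives)` positives and the remainder negatives. The
#' cross-validation fold count is 10 for tables with at least 200 samples
#' and 5 otherwise (smaller cohorts cannot support ten folds per class). A
#' given (table, seed) pair always yields the same split, so the one split
#' can be reused across every injection level and repetition, keeping
#' comparisons paired.
#'
#' @param table A [feature_table()].
#' @param seed Integer seed.
#' @return An object of class `split_plan` with `train_ids`, `test_ids`,
#'   `cv_folds` and `seed`.
#' @export
make_split <- function(table, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$values)
  ids <- table$sample_ids
  pos <- ids[table$outcome == 1L]
  neg <- ids[table$outcome == 0L]
  n_train <- round(0.7 * n)
  n_train_pos <- round(0.7 * length(pos))
  n_train_neg <- n_train - n_train_pos
  stopifnot(n_train_neg >= 1, n_train_neg <= length(neg),
            n_train_pos >= 1)
  with_seed(derive_seed(seed, "split"), {
    train_pos <- sample(pos, n_train_pos)
    train_neg <- sample(neg, n_train_neg)
    train_ids <- ids[ids %in% c(train_pos, train_neg)]
    test_ids <- setdiff(ids, train_ids)
    cv_folds <- if (n >= 200) 10L else 5L
    min_class_train <- min(n_train_pos, n_train_neg)
    if (min_class_train < cv_folds) {
      warning(sprintf(
        "training class with %d members cannot fill %d folds; using %d",
        min_class_train, cv_folds, min_class_train), call. = FALSE)
      cv_folds <- min_class_train
    }
    structure(list(train_ids = train_ids, test_ids = test_ids,
                   cv_folds = cv_folds, seed = as.integer(seed)),
              class = "split_plan")
  })
}

# stratified fold ids in 1..k, deterministic given seed; within each class,
# samples are shuffled then dealt round-robin so fold sizes differ by at
# most one per class
make_stratified_folds <- function(y, k, seed) {
  foldid <- integer(length(y))
  with_seed(derive_seed(seed, "folds", k), {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      foldid[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  foldid
}

#' Fit z-score normalization on a training table and apply it elsewhere
#'
#' Each real feature is transformed to `(x - mean_train) / sd_train` using
#' the sample SD (denominator n - 1) computed on the training rows only;
#' the same parameters are then applied to every other table, so no
#' information flows from test rows into the transform. Constant training
#' features (sd = 0) map to 0 everywhere. Columns with provenance
#' `"random"` are left untouched: injected features are fabricated on the
#' already-normalized scale and re-standardizing them would tie their
#' distribution to the injection level.
#'
#' @param train Training [feature_table()].
#' @param ... Further `feature_table`s to transform with the training
#'   parameters (e.g. the hold-out set).
#' @return A list with `train`, `others` (list of transformed tables, in
#'   input order), and `parameters` (data frame of per-feature mean/sd).
#' @export
zscore_fit_apply <- function(train, ...) {
  stopifnot(inherits(train, "feature_table"))
  others <- list(...)
  real <- feature_names(train, provenance = "real")
  mu <- colMeans(train$values[, real, drop = FALSE])
  sdv <- apply(train$values[, real, drop = FALSE], 2, stats::sd)
  apply_one <- function(tab) {
    v <- tab$values
    for (nm in real) {
      v[, nm] <- if (sdv[nm] > 0) (v[, nm] - mu[nm]) / sdv[nm] else 0
    }
    tab$values <- v
    tab
  }
  list(train = apply_one(train),
       others = lapply(others, apply_one),
       parameters = data.frame(feature = real, mean = unname(mu),
                               sd = unname(sdv)))
}

#' Oversample the minority class to exact balance
#'
#' Rows of the minority class are resampled with replacement (duplicating
#' existing rows, never synthesizing new ones) until both classes have equal
#' counts. Intended for use inside each cross-validation training fold and
#' on the full training split before the final fit — never on validation
#' folds or the hold-out set.
#'
#' @param table A [feature_table()] (both classes present).
#' @param seed Integer seed.
#' @return A [feature_table()] with balanced classes; already-balanced input
#'   is returned unchanged. Duplicated rows get suffixed sample ids.
#' @export
oversample_training <- function(table, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  counts <- table(factor(table$outcome, levels = c(0L, 1L)))
  if (counts[[1]] == counts[[2]]) return(table)
  minority <- if (counts[["1"]] < counts[["0"]]) 1L else 0L
  deficit <- abs(counts[[1]] - counts[[2]])
  idx_min <- which(table$outcome == minority)
  with_seed(derive_seed(seed, "oversample"), {
    extra <- idx_min[sample.int(length(idx_min), deficit, replace = TRUE)]
    v <- rbind(table$values, table$values[extra, , drop = FALSE])
    outc <- c(table$outcome, table$outcome[extra])
    ids <- c(table$sample_ids,
             sprintf("%s_dup%03d", table$sample_ids[extra], seq_along(extra)))
    feature_table(v, outc, sample_ids = ids, provenance = table$provenance,
                  informative_truth = table$informative_truth)
  })
}

#' Fit a random-forest classifier on selected features
#'
#' A probability forest with 500 trees and `floor(sqrt(p))` candidate
#' features per split, deterministic for a given seed.
#'
#' @param train Training [feature_table()].
#' @param selected Non-empty character vector of feature names to use.
#' @param seed Integer seed.
#' @param num_trees Number of trees (default 500).
#' @return An object of class `radinject_model` wrapping the fitted forest.
#' @export
fit_rf <- function(train, selected, seed = 1L, num_trees = 500L) {
  check_selection(selected, "random forest")
  x <- as.data.frame(train$values[, selected, drop = FALSE])
  y <- factor(train$outcome, levels = c(0L, 1L))
  fit <- ranger::ranger(x = x, y = y, num.trees = num_trees,
                        mtry = max(1L, floor(sqrt(length(selected)))),
                        probability = TRUE, seed = seed, num.threads = 1)
  structure(list(kind = "RF", fit = fit, features = selected,
                 prevalence = mean(train$outcome)),
            class = "radinject_model")
}

#' Fit an L1-penalized logistic-regression classifier on selected features
#'
#' The penalty is chosen by internal stratified cross-validation on the
#' binomial deviance over a 100-value log-spaced grid; predicted
#' probabilities come from the logistic link. If the chosen penalty shrinks
#' every coefficient to zero the model predicts the training prevalence for
#' every sample (intercept-only).
#'
#' @inheritParams fit_rf
#' @param cv_folds Folds for the internal penalty CV.
#' @param lambda Optional fixed penalty, bypassing the internal CV.
#' @return An object of class `radinject_model`.
#' @export
fit_lasso_clf <- function(train, selected, seed = 1L, cv_folds = 10L,
                          lambda = NULL) {
  check_selection(selected, "LASSO classifier")
  x <- train$values[, selected, drop = FALSE]
  fit <- lasso_fit(x, train$outcome, seed = seed, cv_folds = cv_folds,
                   lambda = lambda)
  structure(list(kind = "LASSO", fit = fit, features = selected,
                 prevalence = mean(train$outcome)),
            class = "radinject_model")
}

check_selection <- function(selected, what) {
  if (length(selected) == 0L) {
    stop(sprintf(
      "cannot fit %s: the upstream selector returned an empty selection",
      what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Predict class-1 probabilities
#' @param object A `radinject_model`.
#' @param table A [feature_table()] containing the model's features.
#' @param ... Unused.
#' @return Numeric vector of probabilities for the positive class.
#' @export
predict.radinject_model <- function(object, table, ...) {
  x <- table$values[, object$features, drop = FALSE]
  if (object$kind == "RF") {
    pr <- predict(object$fit, data = as.data.frame(x),
                  num.threads = 1)$predictions
    return(unname(pr[, "1"]))
  }
  eta <- drop(x %*% object$fit$coefficients) + object$fit$intercept
  unname(1 / (1 + exp(-eta)))
}

#' Area under the ROC curve by rank concordance
#'
#' `P(score_pos > score_neg) + 0.5 P(tie)`, computed from mid-ranks.
#'
#' @param scores Numeric predicted scores/probabilities.
#' @param labels Binary 0/1 labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a fitted classifier on a table
#'
#' AUC is computed by rank concordance of the predicted probabilities (ties
#' count one half); accuracy, sensitivity and specificity use a probability
#' cutoff of 0.5, with sensitivity the recall of the clinically-significant
#' (positive) class.
#'
#' @param model A `radinject_model`.
#' @param table A [feature_table()] with both outcome classes present.
#' @param cutoff Probability cutoff for the binary metrics (default 0.5).
#' @return Named list: `auc`, `accuracy`, `sensitivity`, `specificity`.
#' @export
evaluate_model <- function(model, table, cutoff = 0.5) {
  stopifnot(inherits(model, "radinject_model"),
            inherits(table, "feature_table"))
  y <- table$outcome
  if (length(unique(y)) < 2L) {
    stop("evaluation table must contain both classes", call. = FALSE)
  }
  p <- predict(model, table)
  pred <- as.integer(p >= cutoff)
  list(auc = auc_score(p, y),
       accuracy = mean(pred == y),
       sensitivity = mean(pred[y == 1L] == 1L),
       specificity = mean(pred[y == 0L] == 0L))
}

#' Stratified cross-validation of a classifier on the training split
#'
#' For each of `k` stratified folds the training part is oversampled to
#' class balance, the classifier is fitted on it, and the untouched
#' validation fold is scored; the reported CV metric is the mean over folds
#' of the per-fold validation metric. Oversampling never touches validation
#' rows.
#'
#' @param train Training [feature_table()].
#' @param selected Feature names to use.
#' @param classifier `"RF"` or `"LASSO"`.
#' @param cv_folds Number of folds.
#' @param seed Integer seed (folds, per-fold oversampling and fits all
#'   derive from it).
#' @param oversample Logical; balance classes inside each training fold
#'   (default `TRUE`).
#' @return Named list of mean CV metrics (`auc`, `accuracy`, `sensitivity`,
#'   `specificity`).
#' @export
cross_validate <- function(train, selected, classifier = c("RF", "LASSO"),
                           cv_folds = 10L, seed = 1L, oversample = TRUE) {
  classifier <- match.arg(classifier)
  foldid <- make_stratified_folds(train$outcome, cv_folds, seed)
  metrics <- lapply(seq_len(cv_folds), function(fold) {
    tr <- subset_table(train, samples = foldid != fold)
    va <- subset_table(train, samples = foldid == fold,
                       allow_single_class = TRUE)
    if (length(unique(va$outcome)) < 2L) return(NULL)
    if (oversample) tr <- oversample_training(tr, derive_seed(seed, "os", fold))
    model <- if (classifier == "RF") {
      fit_rf(tr, selected, seed = derive_seed(seed, "rf", fold))
    } else {
      # nested CV: the inner penalty search uses a coarser 5-fold split
      fit_lasso_clf(tr, selected, seed = derive_seed(seed, "lcv", fold),
                    cv_folds = min(5L, cv_folds, min(table(tr$outcome))))
    }
    evaluate_model(model, va)
  })
  metrics <- Filter(Negate(is.null), metrics)
  stopifnot(length(metrics) >= 1)
  out <- lapply(c("auc", "accuracy", "sensitivity", "specificity"),
                function(m) mean(vapply(metrics, `[[`, numeric(1), m)))
  names(out) <- c("auc", "accuracy", "sensitivity", "specificity")
  out
}
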