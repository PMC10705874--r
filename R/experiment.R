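#' Configure a full injection experiment
#'
#' Describes the complete grid: a data source (a [synthetic_config()] or a
#' CSV path), the injection levels and repetition count, the selectors,
#' classifiers and selection thresholds to cross, and the base seed from
#' which every cell derives its own reproducible RNG stream.
#'
#' @param data A [synthetic_config()], or a list `list(path =, outcome_column =)`
#'   pointing at a feature CSV.
#' @param levels Injection ratios (default [default_injection_levels()]).
#' @param repetitions Repetitions per level (default 20).
#' @param selectors Subset of `c("MRMR", "RFE", "LASSO")`.
#' @param classifiers Subset of `c("RF", "LASSO")`.
#' @param thresholds Maximum selected-feature counts (default `c(20, 50)`).
#' @param alpha Mann-Whitney filter threshold (default 0.05).
#' @param n_permutations Permutations per feature for RF importance.
#' @param base_seed Integer base seed.
#' @param workers Parallel workers for cell evaluation (forked via the
#'   parallel package when > 1; results are identical for any worker count
#'   because every cell's seeds are precomputed from its grid coordinates).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(data = synthetic_config(),
                              levels = default_injection_levels(),
                              repetitions = 20L,
                              selectors = c("MRMR", "RFE", "LASSO"),
                              classifiers = c("RF", "LASSO"),
                              thresholds = c(20L, 50L),
                              alpha = 0.05,
                              n_permutations = 10L,
                              base_seed = 1L,
                              workers = 1L) {
  stopifnot(length(levels) >= 1, all(levels >= 0), all(levels <= 1),
            repetitions >= 1, length(thresholds) >= 1,
            all(selectors %in% c("MRMR", "RFE", "LASSO")),
            all(classifiers %in% c("RF", "LASSO")),
            alpha > 0, alpha <= 1, n_permutations >= 1, workers >= 1)
  structure(
    list(data = data, levels = levels, repetitions = as.integer(repetitions),
         selectors = selectors, classifiers = classifiers,
         thresholds = as.integer(thresholds), alpha = alpha,
         n_permutations = as.integer(n_permutations),
         base_seed = as.integer(base_seed), workers = as.integer(workers)),
    class = "experiment_config"
  )
}

#' Named experiment profiles
#'
#' * `"smoke"`: a minutes-scale sanity grid (2 levels x 2 repetitions,
#'   MRMR + LASSO classifier only) on a small synthetic table.
#' * `"desk"`: a desk-scale study — 260 samples x 60 features with 8
#'   informative features at effect size 1.0, four injection levels
#'   (0/25/50/100%), 10 repetitions, all selector x classifier x threshold
#'   combinations — small enough to run on one CPU in minutes while
#'   exercising the full grid.
#' * `"paper"`: the full-size grid (260 x 265, twelve levels, 20
#'   repetitions).
#'
#' @param name One of `"smoke"`, `"desk"`, `"paper"`.
#' @param base_seed Integer base seed.
#' @return An [experiment_config()].
#' @export
experiment_profile <- function(name = c("desk", "smoke", "paper"),
                               base_seed = 1L) {
  name <- match.arg(name)
  switch(name,
    smoke = experiment_config(
      data = synthetic_config(n_samples = 80, n_features = 20,
                              prevalence = 0.5, n_informative = 4,
                              effect_size = 1.0, n_blocks = 4,
                              seed = derive_seed(base_seed, "data")),
      levels = c(0, 1), repetitions = 2L, selectors = "MRMR",
      classifiers = "LASSO", thresholds = 10L, n_permutations = 3L,
      base_seed = base_seed),
    desk = experiment_config(
      data = synthetic_config(n_samples = 260, n_features = 60,
                              prevalence = 0.49, n_informative = 8,
                              effect_size = 1.0, n_blocks = 10,
                              seed = derive_seed(base_seed, "data")),
      levels = c(0, 0.25, 0.5, 1.0), repetitions = 10L,
      n_permutations = 3L, base_seed = base_seed),
    paper = experiment_config(
      data = synthetic_config(n_samples = 260, n_features = 265,
                              prevalence = 0.49, n_informative = 20,
                              effect_size = 1.0, n_blocks = 10,
                              seed = derive_seed(base_seed, "data")),
      levels = default_injection_levels(), repetitions = 20L,
      base_seed = base_seed)
  )
}

load_experiment_table <- function(config) {
  if (inherits(config$data, "synthetic_config")) {
    generate_table(config$data)
  } else if (is.list(config$data) && !is.null(config$data$path)) {
    read_feature_table(config$data$path,
                       outcome_column = config$data$outcome_column %||%
                         "outcome")
  } else {
    stop("`data` must be a synthetic_config or list(path=, outcome_column=)",
         call. = FALSE)
  }
}

#' Run the full injection experiment
#'
#' Executes the pipeline once per grid cell: the table is split 7:3 once
#' (the same split is reused across every level and repetition so
#' comparisons are paired), real features are z-score normalized with
#' parameters fitted on the training rows, random features are fabricated
#' on the normalized table at the cell's ratio, the Mann-Whitney filter and
#' the cell's selector run on the training rows, and each classifier is
#' cross-validated on the training split (with in-fold oversampling),
#' refitted on the oversampled full training split, and evaluated on the
#' untouched hold-out rows. Feature importance (permutation-based for RF,
#' coefficient magnitude for LASSO) is normalized to percentages.
#'
#' Partial failures — an empty filter or an empty LASSO selection — are
#' recorded per cell and do not abort the run.
#'
#' @param config An [experiment_config()].
#' @param progress Print per-cell progress to stderr (default `FALSE`).
#' @return An object of class `experiment_grid`: list with `config`,
#'   `split`, `evaluations` (tidy data frame, one row per completed cell),
#'   `selections` (list of `selection_result`s keyed by selection id),
#'   `importances` (list of percentage vectors keyed by cell id),
#'   `provenance` (feature provenance of the most-injected table), and
#'   `failures` (data frame of failed cells with reasons).
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  table <- load_experiment_table(config)
  split <- make_split(table, seed = derive_seed(config$base_seed, "split"))
  train0 <- subset_table(table, samples = split$train_ids)
  norm <- zscore_fit_apply(train0, table)
  norm_table <- norm$others[[1]]

  cells <- list()
  for (li in seq_along(config$levels)) {
    for (rep_i in seq_len(config$repetitions)) {
      cells[[length(cells) + 1L]] <- list(li = li, rep_i = rep_i)
    }
  }

  eval_one <- function(cell) {
    li <- cell$li; rep_i <- cell$rep_i
    level <- config$levels[li]
    spec <- injection_spec(level, rep_i,
                           seed = derive_seed(config$base_seed, "inject",
                                              li, rep_i))
    injected <- fabricate_random_features(norm_table, spec)
    train <- subset_table(injected, samples = split$train_ids)
    test <- subset_table(injected, samples = split$test_ids)
    survivors <- mann_whitney_filter(train, alpha = config$alpha)

    evals <- list(); sels <- list(); imps <- list(); fails <- list()
    for (selector in config$selectors) {
      for (k in config$thresholds) {
        sel_id <- sprintf("L%03.0f_R%02d_%s_k%d", level * 100, rep_i,
                          selector, k)
        sel_seed <- derive_seed(config$base_seed, "select", li, rep_i,
                                selector, k)
        sel <- tryCatch({
          if (length(survivors) == 0L) stop("no features pass the filter")
          switch(selector,
            MRMR = select_mrmr(train, survivors, k),
            RFE = select_rfe(train, survivors, k, seed = sel_seed),
            LASSO = suppressWarnings(
              select_lasso(train, survivors, k, seed = sel_seed,
                           cv_folds = split$cv_folds)))
        }, error = function(e) e)
        if (inherits(sel, "error") || length(sel$selected) == 0L) {
          reason <- if (inherits(sel, "error")) conditionMessage(sel) else
            "empty selection"
          for (clf in config$classifiers) {
            fails[[length(fails) + 1L]] <- data.frame(
              level = level, repetition = rep_i, selector = selector,
              threshold = k, classifier = clf, reason = reason)
          }
          next
        }
        sels[[sel_id]] <- sel
        contam <- contamination_ratio(sel, injected$provenance)
        for (clf in config$classifiers) {
          cell_id <- sprintf("%s_%s", sel_id, clf)
          clf_seed <- derive_seed(config$base_seed, "model", li, rep_i,
                                  selector, k, clf)
          row <- tryCatch({
            cv <- cross_validate(train, sel$selected, classifier = clf,
                                 cv_folds = split$cv_folds, seed = clf_seed)
            final_train <- oversample_training(train,
                                               derive_seed(clf_seed, "final"))
            model <- if (clf == "RF") {
              fit_rf(final_train, sel$selected, seed = clf_seed)
            } else {
              fit_lasso_clf(final_train, sel$selected, seed = clf_seed,
                            cv_folds = split$cv_folds)
            }
            tst <- evaluate_model(model, test)
            imps[[cell_id]] <- model_importance(
              model, train, n_permutations = config$n_permutations,
              seed = derive_seed(clf_seed, "imp"))
            data.frame(
              cell_id = cell_id, level = level, repetition = rep_i,
              selector = selector, threshold = k, classifier = clf,
              n_candidates = length(survivors),
              n_selected = length(sel$selected),
              n_random_selected = sum(
                injected$provenance[sel$selected] == "random"),
              contamination = contam,
              cv_auc = cv$auc, cv_accuracy = cv$accuracy,
              cv_sensitivity = cv$sensitivity,
              cv_specificity = cv$specificity,
              test_auc = tst$auc, test_accuracy = tst$accuracy,
              test_sensitivity = tst$sensitivity,
              test_specificity = tst$specificity,
              stringsAsFactors = FALSE)
          }, error = function(e) e)
          if (inherits(row, "error")) {
            fails[[length(fails) + 1L]] <- data.frame(
              level = level, repetition = rep_i, selector = selector,
              threshold = k, classifier = clf,
              reason = conditionMessage(row))
          } else {
            evals[[length(evals) + 1L]] <- row
          }
        }
      }
    }
    if (progress) {
      message(sprintf("level %.2f repetition %d: %d evaluations, %d failures",
                      level, rep_i, length(evals), length(fails)))
    }
    list(evals = evals, sels = sels, imps = imps, fails = fails,
         provenance = injected$provenance)
  }

  results <- if (config$workers > 1L) {
    parallel::mclapply(cells, eval_one, mc.cores = config$workers)
  } else {
    lapply(cells, eval_one)
  }

  evaluations <- do.call(rbind, unlist(lapply(results, `[[`, "evals"),
                                       recursive = FALSE))
  failures <- do.call(rbind, unlist(lapply(results, `[[`, "fails"),
                                    recursive = FALSE))
  selections <- do.call(c, lapply(results, `[[`, "sels"))
  importances <- do.call(c, lapply(results, `[[`, "imps"))
  # provenance covering the widest injected table observed
  prov_all <- results[[which.max(vapply(results, function(r)
    length(r$provenance), integer(1)))]]$provenance

  structure(
    list(config = config, split = split,
         evaluations = evaluations %||% data.frame(),
         selections = selections %||% list(),
         importances = importances %||% list(),
         provenance = prov_all,
         failures = failures %||%
           data.frame(level = numeric(), repetition = integer(),
                      selector = character(), threshold = integer(),
                      classifier = character(), reason = character())),
    class = "experiment_grid"
  )
}

#' @export
print.experiment_grid <- function(x, ...) {
  cat(sprintf(
    "<experiment_grid> %d evaluations (%d failures) over %d levels x %d repetitions\n",
    nrow(x$evaluations), nrow(x$failures), length(x$config$levels),
    x$config$repetitions))
  invisible(x)
}

#' Selection stability and contamination by level
#'
#' For every (selector, threshold, level): the multi-set Jaccard similarity
#' of the selected radiomics features across repetitions (injected features
#' excluded) and the mean contamination ratio.
#'
#' @param grid An `experiment_grid`.
#' @return Data frame with columns `selector`, `threshold`, `level`, `jsc`,
#'   `mean_contamination`, `n_repetitions`.
#' @export
summarize_stability <- function(grid) {
  stopifnot(inherits(grid, "experiment_grid"))
  cfg <- grid$config
  out <- list()
  for (selector in cfg$selectors) {
    for (k in cfg$thresholds) {
      for (level in cfg$levels) {
        ids <- sprintf("L%03.0f_R%02d_%s_k%d", level * 100,
                       seq_len(cfg$repetitions), selector, k)
        sels <- grid$selections[intersect(ids, names(grid$selections))]
        if (length(sels) < 2L) next
        jsc <- selection_stability(sels, grid$provenance)
        contam <- vapply(sels, contamination_ratio,
                         numeric(1), provenance = grid$provenance)
        out[[length(out) + 1L]] <- data.frame(
          selector = selector, threshold = k, level = level,
          jsc = jsc, mean_contamination = mean(contam),
          n_repetitions = length(sels), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Aggregated feature importance by injection level
#'
#' Applies [aggregate_importance()] across all evaluations at each level
#' (pooling repetitions, selectors, classifiers and thresholds).
#'
#' @param grid An `experiment_grid`.
#' @return Data frame with one row per (level, rank 1-10) for real and
#'   random features plus the mean total random contribution per level.
#' @export
summarize_importance <- function(grid) {
  stopifnot(inherits(grid, "experiment_grid"))
  out <- list()
  for (level in grid$config$levels) {
    ids <- grid$evaluations$cell_id[grid$evaluations$level == level]
    imps <- grid$importances[intersect(ids, names(grid$importances))]
    if (length(imps) == 0L) next
    agg <- aggregate_importance(imps, grid$provenance)
    n_real <- length(agg$top10_real)
    out[[length(out) + 1L]] <- data.frame(
      level = level,
      rank = c(seq_len(n_real), seq_len(10L)),
      kind = c(rep("real", n_real), rep("random", 10L)),
      feature = c(names(agg$top10_real), rep(NA_character_, 10L)),
      mean_importance = c(unname(agg$top10_real), agg$top10_random_mean),
      total_random_contribution = agg$total_random_contribution,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Importance extremes by model combination
#'
#' For each (selector, classifier, threshold) combination, the largest
#' per-feature mean importance among real features and among random
#' features, pooled over all levels with injected features.
#'
#' @param grid An `experiment_grid`.
#' @return Data frame with `max_mean_real` and `max_mean_random` per
#'   combination.
#' @export
importance_by_combination <- function(grid) {
  stopifnot(inherits(grid, "experiment_grid"))
  ev <- grid$evaluations
  out <- list()
  for (selector in grid$config$selectors) {
    for (clf in grid$config$classifiers) {
      for (k in grid$config$thresholds) {
        ids <- ev$cell_id[ev$selector == selector & ev$classifier == clf &
                            ev$threshold == k & ev$level > 0]
        imps <- grid$importances[intersect(ids, names(grid$importances))]
        if (length(imps) == 0L) next
        agg <- aggregate_importance(imps, grid$provenance)
        out[[length(out) + 1L]] <- data.frame(
          selector = selector, classifier = clf, threshold = k,
          max_mean_real = if (length(agg$top10_real)) agg$top10_real[[1]] else 0,
          max_mean_random = agg$top10_random_mean[1],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' ANOVA of a performance metric across injection levels
#'
#' One one-way ANOVA per model combination, testing whether the metric
#' differs across injection levels, Bonferroni-corrected for the number of
#' combinations tested.
#'
#' @param grid An `experiment_grid`.
#' @param metric Evaluation column to test (default `"test_auc"`).
#' @param families Bonferroni family size; defaults to the number of
#'   combinations present.
#' @return Data frame with one row per combination: `f`, `p`, `p_adjusted`,
#'   `significant`.
#' @export
summarize_anova <- function(grid, metric = "test_auc", families = NULL) {
  stopifnot(inherits(grid, "experiment_grid"))
  ev <- grid$evaluations
  stopifnot(metric %in% names(ev))
  combos <- unique(ev[, c("selector", "classifier", "threshold")])
  combos <- combos[order(combos$selector, combos$classifier,
                         combos$threshold), , drop = FALSE]
  families <- families %||% nrow(combos)
  out <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- ev[ev$selector == combos$selector[i] &
                ev$classifier == combos$classifier[i] &
                ev$threshold == combos$threshold[i], ]
    lvl_counts <- table(sub$level)
    keep_levels <- names(lvl_counts)[lvl_counts >= 2]
    sub <- sub[as.character(sub$level) %in% keep_levels, ]
    if (length(keep_levels) < 2L) next
    res <- anova_bonferroni(sub[[metric]], sub$level, families = families)
    out[[length(out) + 1L]] <- data.frame(
      selector = combos$selector[i], classifier = combos$classifier[i],
      threshold = combos$threshold[i], metric = metric,
      f = res$f, p = res$p, p_adjusted = res$p_adjusted,
      significant = res$significant, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
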