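#' Write the experiment grid to tidy CSV files
#'
#' Emits `evaluations.csv` (one row per completed cell), `stability.csv`
#' (JSC and mean contamination per selector/threshold/level),
#' `importance_by_level.csv`, `importance_by_combination.csv`, `anova.csv`
#' (hold-out AUC across levels per combination), `importances.csv` (the
#' per-cell percentage vectors in long form) and `failures.csv`. Row order
#' and number formatting are deterministic, so identical grids produce
#' byte-identical files.
#'
#' @param grid An `experiment_grid`.
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_experiment_csvs <- function(grid, dir) {
  stopifnot(inherits(grid, "experiment_grid"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  ev <- grid$evaluations
  ev <- ev[order(ev$cell_id), , drop = FALSE]
  emit(ev, "evaluations.csv")
  emit(summarize_stability(grid), "stability.csv")
  imp_lvl <- summarize_importance(grid)
  if (!is.null(imp_lvl)) emit(imp_lvl, "importance_by_level.csv")
  imp_cmb <- importance_by_combination(grid)
  if (!is.null(imp_cmb)) emit(imp_cmb, "importance_by_combination.csv")
  an <- summarize_anova(grid)
  if (!is.null(an)) emit(an, "anova.csv")
  if (length(grid$importances) > 0) {
    long <- do.call(rbind, lapply(sort(names(grid$importances)), function(id) {
      im <- grid$importances[[id]]
      data.frame(cell_id = id, feature = names(im),
                 provenance = unname(grid$provenance[names(im)]),
                 importance_pct = unname(im), stringsAsFactors = FALSE)
    }))
    emit(long, "importances.csv")
  }
  emit(grid$failures, "failures.csv")
  invisible(paths)
}

#' Render the experiment report
#'
#' Writes all tidy CSVs (see [write_experiment_csvs()]), a plain-text
#' summary of the headline quantities, and — when ggplot2 is available —
#' PDF figures: contamination-vs-level and JSC-vs-level curves per
#' selector/threshold, hold-out and CV AUC boxplots per combination and
#' level, and top-10 importance bars per level.
#'
#' @param grid An `experiment_grid`.
#' @param dir Output directory.
#' @return Character vector of written paths, invisibly.
#' @export
render_report <- function(grid, dir) {
  stopifnot(inherits(grid, "experiment_grid"))
  paths <- write_experiment_csvs(grid, dir)
  stab <- summarize_stability(grid)
  an <- summarize_anova(grid)
  ev <- grid$evaluations

  summary_path <- file.path(dir, "summary.txt")
  con <- file(summary_path, "w")
  on.exit(close(con), add = TRUE)
  w <- function(...) writeLines(sprintf(...), con)
  w("Irrelevant-feature injection experiment summary")
  w("================================================")
  w("Grid: %d levels x %d repetitions x %d selectors x %d classifiers x %d thresholds",
    length(grid$config$levels), grid$config$repetitions,
    length(grid$config$selectors), length(grid$config$classifiers),
    length(grid$config$thresholds))
  w("Completed evaluations: %d; failed cells: %d",
    nrow(ev), nrow(grid$failures))
  w("")
  top_level <- max(grid$config$levels)
  for (selector in grid$config$selectors) {
    s0 <- stab[stab$selector == selector & stab$level == 0, ]
    s1 <- stab[stab$selector == selector & stab$level == top_level, ]
    w("%s: mean contamination %.3f -> %.3f, JSC %.3f -> %.3f (level 0 -> %.0f%%)",
      selector, mean(s0$mean_contamination), mean(s1$mean_contamination),
      mean(s0$jsc), mean(s1$jsc), top_level * 100)
  }
  w("")
  w("Mean hold-out AUC at level 0: %.3f; at injected levels: %.3f",
    mean(ev$test_auc[ev$level == 0]), mean(ev$test_auc[ev$level > 0]))
  if (!is.null(an)) {
    w("Combinations with Bonferroni-adjusted p > 0.05 for AUC across levels: %d of %d",
      sum(!an$significant), nrow(an))
  }
  paths <- c(paths, summary_path)

  if (requireNamespace("ggplot2", quietly = TRUE)) {
    paths <- c(paths, render_report_plots(grid, stab, dir))
  }
  invisible(paths)
}

render_report_plots <- function(grid, stab, dir) {
  g <- ggplot2::ggplot
  aes <- ggplot2::aes
  ev <- grid$evaluations
  stab$threshold <- factor(stab$threshold)
  written <- character(0)
  save_plot <- function(plot, name, width = 7, height = 5) {
    p <- file.path(dir, name)
    ggplot2::ggsave(p, plot, width = width, height = height)
    written <<- c(written, p)
  }
  save_plot(
    g(stab, aes(x = level, y = mean_contamination, colour = selector,
                linetype = threshold)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "Injection level", y = "Mean contamination ratio"),
    "contamination.pdf")
  save_plot(
    g(stab, aes(x = level, y = jsc, colour = selector,
                linetype = threshold)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "Injection level", y = "Multi-set Jaccard (JSC)"),
    "jsc.pdf")
  ev_long <- rbind(
    data.frame(ev, set = "cv", auc = ev$cv_auc, acc = ev$cv_accuracy),
    data.frame(ev, set = "test", auc = ev$test_auc, acc = ev$test_accuracy))
  combo <- interaction(ev_long$selector, ev_long$classifier,
                       ev_long$threshold, sep = "/")
  ev_long$combo <- combo
  save_plot(
    g(ev_long, aes(x = factor(level), y = auc, fill = set)) +
      ggplot2::geom_boxplot(outlier.size = 0.4) +
      ggplot2::facet_wrap(~combo) +
      ggplot2::labs(x = "Injection level", y = "AUC"),
    "auc_by_level.pdf", width = 10, height = 8)
  imp <- summarize_importance(grid)
  if (!is.null(imp)) {
    save_plot(
      g(imp, aes(x = rank, y = mean_importance, fill = kind)) +
        ggplot2::geom_col(position = "dodge") +
        ggplot2::facet_wrap(~level) +
        ggplot2::labs(x = "Rank", y = "Mean importance (%)"),
      "importance_top10.pdf", width = 8, height = 6)
  }
  written
}
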