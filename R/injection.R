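#' Specify one irrelevant-feature injection
#'
#' An injection spec names one (level, repetition) perturbation of a feature
#' table: the ratio of fabricated random features to add relative to the
#' table's real-feature count, a repetition index, and the RNG seed that
#' determines which real features are picked as range templates.
#'
#' @param ratio Fraction in `[0, 1]`: the number of injected features is
#'   `round_half_up(ratio * n_real_features)`.
#' @param repetition_index Positive integer identifying the repetition.
#' @param seed Integer RNG seed for template picks and uniform draws.
#' @return An object of class `injection_spec`.
#' @export
injection_spec <- function(ratio, repetition_index = 1L, seed = 1L) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio < 0 || ratio > 1) {
    stop("`ratio` must be a single fraction in [0, 1]", call. = FALSE)
  }
  stopifnot(repetition_index >= 1)
  structure(
    list(ratio = ratio, repetition_index = as.integer(repetition_index),
         seed = as.integer(seed)),
    class = "injection_spec"
  )
}

#' Fabricate random irrelevant features and append them to a table
#'
#' For each new column one real feature is picked uniformly at random (with
#' replacement across columns) as a range template, and the column is filled
#' with i.i.d. draws from Uniform(min, max) of that template's observed
#' values over the whole table. Injected columns are named
#' `random_0001, ...`, flagged with provenance `"random"`, and are
#' independent of the outcome by construction. Original columns are left
#' untouched. A template with zero range yields a degenerate uniform (the
#' constant value), not an error.
#'
#' @param table A [feature_table()].
#' @param spec An [injection_spec()].
#' @return A new [feature_table()] with
#'   `round_half_up(ratio * n_real_features)` appended random columns. The
#'   realized template assignment (random column -> template real feature) is
#'   attached as attribute `"template_assignment"`, and the spec as
#'   `"injection_spec"`, for provenance.
#' @export
fabricate_random_features <- function(table, spec) {
  stopifnot(inherits(table, "feature_table"), inherits(spec, "injection_spec"))
  real <- feature_names(table, provenance = "real")
  p_real <- length(real)
  m <- round_half_up(spec$ratio * p_real)
  if (m == 0L) {
    out <- table
    attr(out, "template_assignment") <- character(0)
    attr(out, "injection_spec") <- spec
    return(out)
  }
  n <- nrow(table$values)
  with_seed(spec$seed, {
    templates <- real[sample.int(p_real, m, replace = TRUE)]
    rand_vals <- vapply(templates, function(tmpl) {
      rng <- range(table$values[, tmpl])
      stats::runif(n, rng[1], rng[2])
    }, numeric(n))
    rand_vals <- matrix(rand_vals, nrow = n)
    new_names <- sprintf("random_%04d", seq_len(m))
    colnames(rand_vals) <- new_names
    values <- cbind(table$values, rand_vals)
    prov <- c(table$provenance, stats::setNames(rep("random", m), new_names))
    info <- table$informative_truth
    if (!is.null(info)) {
      info <- c(info, stats::setNames(rep(FALSE, m), new_names))
    }
    out <- feature_table(values, table$outcome, sample_ids = table$sample_ids,
                         provenance = prov, informative_truth = info)
    attr(out, "template_assignment") <- stats::setNames(templates, new_names)
    attr(out, "injection_spec") <- spec
    out
  })
}

#' Default injection levels
#'
#' The twelve ratios used throughout: 10% increments from 0% to 100% plus an
#' additional 5% level.
#' @return Numeric vector of length 12.
#' @export
default_injection_levels <- function() {
  c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
}

#' Build the full grid of injection specs
#'
#' One spec per (level, repetition) cell with a deterministic per-cell seed
#' derived from `(base_seed, level index, repetition index)`, so that each
#' repetition draws a different random sample of template features while the
#' whole grid is reproducible from one base seed.
#'
#' @param levels Non-empty numeric vector of ratios in `[0, 1]`; defaults to
#'   [default_injection_levels()].
#' @param repetitions Number of repetitions per level (default 20).
#' @param base_seed Integer base seed.
#' @return A list of `length(levels) * repetitions` [injection_spec()]s,
#'   ordered level-major.
#' @export
injection_grid <- function(levels = default_injection_levels(),
                           repetitions = 20L, base_seed = 1L) {
  stopifnot(length(levels) >= 1, all(levels >= 0), all(levels <= 1),
            repetitions >= 1)
  specs <- vector("list", length(levels) * repetitions)
  idx <- 1L
  for (li in seq_along(levels)) {
    for (rep_i in seq_len(repetitions)) {
      specs[[idx]] <- injection_spec(
        ratio = levels[li], repetition_index = rep_i,
        seed = derive_seed(base_seed, "inject", li, rep_i))
      idx <- idx + 1L
    }
  }
  specs
}
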