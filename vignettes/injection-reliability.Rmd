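---
title: "Stress-testing radiomics feature selection with injected irrelevant features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress-testing radiomics feature selection with injected irrelevant features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radinject)
```

## The question

Radiomics models are built from hundreds to thousands of quantitative
features extracted from medical images, of which only a fraction carry any
association with the clinical endpoint — here, distinguishing clinically
significant prostate cancer (Gleason score >= 7) from non-significant
lesions. A natural reliability concern follows: if a feature table is
progressively diluted with columns that are *irrelevant by construction*,
how badly do the standard selection-and-modelling pipelines degrade? Do
selectors pick up the irrelevant columns (contamination)? Does the set of
radiomics features they pick become unstable across repetitions? Does
hold-out performance drop? Do the irrelevant columns claim model importance
that should belong to real features?

`radinject` packages this experiment as a reusable, fully seeded pipeline.

## The pipeline, step by step

1. **Data.** A feature table of lesions x continuous features with a binary
   outcome, either loaded from CSV or drawn from the package's synthetic
   generator (below). The table is split **once** into 70% training / 30%
   hold-out rows, stratified by outcome; that single split is reused across
   every injection level and repetition, so all comparisons are paired and
   differences between levels cannot come from split-to-split noise.
2. **Normalization.** Real features are z-scored with mean and sample SD
   (denominator n − 1) estimated on the training rows only; constant
   features map to 0. Test rows are transformed with the training
   parameters, never their own.
3. **Injection.** At ratio r, `round_half_up(r * p_real)` fabricated
   columns are appended. Each fabricated column picks one real feature
   uniformly at random (with replacement across columns) as a *template*
   and draws i.i.d. values from Uniform(min, max) of that template's
   observed values. Templates are drawn per repetition, so the twelve
   default levels (0%, 5%, 10%, ..., 100%) x 20 repetitions give 240
   distinct perturbed tables. Injection happens **after** normalization and
   the fabricated columns are not re-standardized: this keeps the real
   features' normalization independent of the injection level, and the
   fabricated columns already live on the normalized scale because their
   templates do. Template ranges are computed from the whole table; since a
   fabricated column is independent of the outcome by construction, this
   carries no label information into the hold-out rows.
4. **Filtering and selection.** On the training rows, features whose
   two-sided Mann–Whitney U p-value against the outcome is >= 0.05 are
   discarded. The survivors go into one of three selectors, each capped at
   a maximum of k = 20 or 50 features:
   * **MRMR** — greedy forward selection; relevance is the one-way ANOVA F
     statistic against the outcome, redundancy the mean |Pearson r| with
     the already-selected set, combined by subtraction (the difference
     criterion). This is the common continuous-feature formulation and
     avoids discretization choices.
   * **RFE** — repeatedly fit a 500-tree random forest and drop the
     lowest-importance 10% of features (at least one) until <= k remain.
   * **LASSO** — L1-penalized logistic regression with the penalty chosen
     by internal stratified CV on the binomial deviance over a 100-value
     grid; non-zero-coefficient features, capped at the k largest by
     |coefficient|. LASSO may legitimately return fewer than k features,
     or none — an empty selection is recorded as a failed cell, not an
     error.
   All ties anywhere break lexicographically by feature name, so results
   are reproducible to the byte.
5. **Modelling.** Each selected set feeds a random forest (500 trees,
   sqrt(p) mtry, probability output) and an L1-logistic classifier — with
   three selectors, two classifiers and two thresholds, 12 model
   combinations per perturbed table. Training uses stratified k-fold CV
   (k = 10 for n >= 200, else 5) with the minority class oversampled to
   exact balance by duplication *inside each training fold only*; the
   reported CV metric is the mean over folds of the validation-fold metric.
   The final model is refitted on the (oversampled) full training split and
   evaluated once on the untouched hold-out rows. AUC is computed by rank
   concordance (ties count 1/2); accuracy, sensitivity and specificity use
   a 0.5 probability cutoff.
6. **Reliability statistics.**
   * *Contamination ratio* — the fraction of a selection that is injected
     columns.
   * *Stability* — the multi-set Jaccard coefficient across the
     repetitions at one level: |intersection| / |union| of the selected
     sets, with injected columns removed first so the statistic tracks the
     consistency of the *radiomics* features.
   * *Importance* — permutation importance (mean accuracy drop over
     permutations of one column, computed on the training split, negatives
     floored at 0) for forests; |coefficient| for LASSO models; normalized
     to share-of-total percentages summing to 100. The share-of-total
     convention (rather than max = 100) is what makes per-feature
     contributions addable and comparable across models. Top-10 summaries
     average each real feature's share across evaluations (absent = 0) and
     average the 10 largest injected-column shares position-wise.
   * *Performance comparisons* — one-way ANOVA of a metric across
     injection levels, per model combination, Bonferroni-corrected for the
     number of combinations tested.

## The synthetic generator

The public tables this design targets are 260 lesions x 265 features with
49% positive outcomes, and 100 lesions x 7106 features with 80% positives.
The generator emulates that *structure* with a class-conditional Gaussian
model — the real datasets' generative process is unknown, so this is an
explicit modelling assumption, not an inference:

* features fall into equicorrelated blocks (radiomics features derived
  from the same image region are strongly inter-correlated); within-block
  correlation defaults to 0.5;
* a configurable subset of features is *informative*: their latent mean is
  shifted by `effect_size` standard deviations in the positive class;
* the positive count is realized exactly as `round(prevalence * n)`, not
  by Bernoulli draws, so small stratified splits are stable;
* each feature gets its own log-uniform SD (default range 0.1–100) and an
  arbitrary location, so raw columns span heterogeneous scales and
  z-scoring is a meaningful, testable step.

What the generator does **not** emulate: heavy tails, skewed and bounded
feature distributions, non-linear feature–outcome relations, and the
long-range correlation structure of real radiomics tables. Tests passing
on synthetic tables therefore validate the *pipeline machinery and the
reliability statistics*, not claims about any particular clinical dataset.

## Problem sizes and profiles

Three named profiles ship with the package:

* `smoke` — 80 x 20, two levels, two repetitions, one selector/classifier:
  a seconds-scale sanity check.
* `desk` — 260 samples x 60 features, 8 informative at effect size 1.0,
  prevalence 0.49, levels 0/25/50/100%, 10 repetitions, all 12 model
  combinations (480 model fits). This is the package's standard study
  size: large enough that contamination, stability and ANOVA summaries are
  well-behaved, small enough to run on a single CPU in a few minutes. With
  8 of 60 features informative and ~5% of null features passing the
  univariate filter by chance, the filter funnel behaves qualitatively
  like the full-size problem.
* `paper` — 260 x 265, twelve levels, 20 repetitions (2,880 model fits):
  the full-size study grid, dimensioned like the larger public prostate
  radiomics table.

The desk profile uses 3 permutations per feature for permutation
importance (10 by default elsewhere): importance summaries average over
hundreds of (feature, cell) pairs, so the Monte-Carlo error of a small
per-cell permutation count washes out in the aggregates.

## Numerical choices and degenerate inputs

* **Mann–Whitney p-values** use the exact permutation null (enumeration
  over rank assignments, mid-ranks for ties) when both groups have <= 8
  members, and the tie-corrected normal approximation with continuity
  correction otherwise. Constant features get p = 1 and fall out of the
  filter rather than erroring.
* **round-half-up** for injected-feature counts: `round()`'s
  round-half-to-even would make 5% of some feature counts depend on IEEE
  representation.
* **Zero-width template ranges** produce constant fabricated columns
  (degenerate uniform), not errors.
* **Zero-variance selection candidates** are excluded from MRMR up front:
  their relevance is 0 and their correlation with anything is undefined.
* **glmnet single-feature fits** are padded with a constant dummy column
  (stripped from all results) because glmnet requires two columns.
* **Oversampling in the final refit**: the full training split is
  oversampled before the final model is fitted, mirroring what happens
  inside each CV fold; the hold-out set is never touched.
* **Seeds**: every cell of the experiment grid derives its seed by hashing
  (base seed, level index, repetition, selector, threshold, classifier),
  so any cell can be recomputed in isolation and results are independent
  of execution order and worker count.

## Design choices where the design was open

* The filter and the selectors see **training rows only**. Running them on
  the full table would leak hold-out information into the selected sets
  and inflate hold-out performance estimates.
* One split per (table, base seed) reused across the whole grid (rather
  than re-splitting per repetition) isolates the injection effect from
  split noise; repetitions differ in their fabricated columns and
  model/fold seeds.
* The CV "training" metrics reported are validation-fold means, not
  resubstitution values.
* Uniform is the only injected-feature distribution; the generator
  interface would admit others (Gaussian, permuted real columns), but they
  are out of scope here.
* ANOVA families default to the number of model combinations tested; the
  family size is exposed because different reporting conventions exist.

## Null calibration

The ANOVA machinery is calibrated on no-signal tables (`effect_size = 0`):
many small grids are simulated and the across-level ANOVA on hold-out AUC
should reject at roughly the nominal 5% rate, with the grand mean AUC near
0.5. The null grids use only strictly positive injection levels: at level
0 the injection step is a no-op, so repetitions there would be identical
tables differing only in fitting seeds — degenerate near-duplicate groups
that say nothing about the statistic's size under exchangeable
perturbations. The test suite runs 100 such grids at 100 samples x 40
features, two levels x three repetitions, MRMR + random forest.

## A worked desk-scale run

```{r desk, eval = FALSE}
grid <- run_experiment(experiment_profile("desk", base_seed = 1))
summarize_stability(grid)
summarize_anova(grid, metric = "test_auc")
render_report(grid, "desk_report")
```

Qualitatively, a desk run reproduces the reliability picture this design
probes: mean contamination rises from exactly 0 at level 0 to its maximum
at 100% injection; the multi-set Jaccard of the selected radiomics
features drifts down slightly as the injected columns multiply; hold-out
AUC stays statistically flat across levels for nearly all combinations
(Bonferroni-adjusted p > 0.05); and the largest mean importance share held
by any injected column stays well below that of the top real features.

## Known limitations

* Selector and classifier hyperparameters are fixed (500 trees, 10%
  elimination step, deviance-CV penalty); tuning them is explicitly out of
  scope.
* The one-way ANOVA treats repetitions as independent observations per
  level; a repeated-measures formulation would model the shared split, at
  the cost of a heavier assumption load.
* Synthetic tables are Gaussian; see above for what that does and does not
  validate.
* Permutation importance is computed on training rows; validation-based
  importance would shrink the importance of overfitted features and is a
  worthwhile extension.
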