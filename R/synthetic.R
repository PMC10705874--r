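#' Configuration for synthetic radiomics-like tables
#'
#' Describes a class-conditional Gaussian generator with equicorrelated
#' feature blocks. Radiomics features are typically strongly inter-correlated
#' (many texture/intensity descriptors are computed from the same voxels), so
#' features are grouped into blocks sharing a latent factor; a known subset is
#' "informative", shifted between outcome classes by a standardized effect
#' size. Raw feature scales are heterogeneous (per-feature SDs drawn
#' log-uniformly) so that z-score normalization is a meaningful step, as it is
#' for real radiomics tables whose features span orders of magnitude.
#'
#' @param n_samples Number of samples (lesions). Default 260, the size of the
#'   larger public prostate MRI radiomics table this generator emulates.
#' @param n_features Number of real features. Default 265.
#' @param prevalence Fraction of positive (clinically significant) outcomes in
#'   (0,1); realized exactly as `round(prevalence * n_samples)` positives so
#'   that scaled-down runs have stable stratified splits. Default 0.49.
#' @param n_informative Number of features with a true class association.
#' @param effect_size Standardized mean shift (in latent SD units) of
#'   informative features in the positive class. 0 gives a pure null table.
#' @param n_blocks Number of equicorrelated feature blocks.
#' @param within_block_correlation Pairwise correlation inside a block, in
#'   `[0, 1)`.
#' @param feature_scale_range Length-2 positive numeric; per-feature SDs are
#'   drawn log-uniformly between the two values.
#' @param seed Integer seed; the same config + seed reproduces the table
#'   bitwise.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 260, n_features = 265,
                             prevalence = 0.49, n_informative = 20,
                             effect_size = 1.0, n_blocks = 10,
                             within_block_correlation = 0.5,
                             feature_scale_range = c(0.1, 100),
                             seed = 1L) {
  stopifnot(n_samples >= 2, n_features >= 1,
            prevalence > 0, prevalence < 1,
            n_informative >= 0, effect_size >= 0, n_blocks >= 1,
            length(feature_scale_range) == 2, all(feature_scale_range > 0))
  if (n_informative > n_features) {
    stop("`n_informative` cannot exceed `n_features`", call. = FALSE)
  }
  if (within_block_correlation < 0 || within_block_correlation >= 1) {
    stop("`within_block_correlation` must lie in [0, 1) for a positive-definite block covariance",
         call. = FALSE)
  }
  n_pos <- round(prevalence * n_samples)
  if (n_pos < 1 || n_pos > n_samples - 1) {
    stop("`prevalence` leaves one class empty at this sample size",
         call. = FALSE)
  }
  structure(
    list(n_samples = as.integer(n_samples), n_features = as.integer(n_features),
         prevalence = prevalence, n_informative = as.integer(n_informative),
         effect_size = effect_size, n_blocks = as.integer(n_blocks),
         within_block_correlation = within_block_correlation,
         feature_scale_range = sort(as.numeric(feature_scale_range)),
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate a synthetic radiomics-like feature table
#'
#' Draws a [feature_table()] from the class-conditional Gaussian model in
#' [synthetic_config()]: the realized positive count is exactly
#' `round(prevalence * n_samples)`; features within a block are
#' equicorrelated at the configured correlation via a shared latent factor;
#' informative features get a `+effect_size` latent mean shift in the
#' positive class; every feature is then rescaled to its own log-uniform SD
#' and given an arbitrary location so raw columns live on heterogeneous
#' scales.
#'
#' @param config A [synthetic_config()].
#' @return A [feature_table()] with `informative_truth` set and all
#'   provenance `"real"`.
#' @examples
#' tab <- generate_table(synthetic_config(n_samples = 60, n_features = 12,
#'                                        n_informative = 3, seed = 7))
#' tab
#' @export
generate_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_samples
  p <- config$n_features
  rho <- config$within_block_correlation
  with_seed(config$seed, {
    n_pos <- round(config$prevalence * n)
    outcome <- integer(n)
    outcome[sample.int(n, n_pos)] <- 1L

    block_of <- rep(seq_len(config$n_blocks), length.out = p)
    informative <- seq_len(p) <= config$n_informative

    # equicorrelated blocks: z_j = sqrt(rho) u_b + sqrt(1-rho) e_j, unit var
    u <- matrix(stats::rnorm(n * config$n_blocks), n, config$n_blocks)
    e <- matrix(stats::rnorm(n * p), n, p)
    z <- sqrt(rho) * u[, block_of, drop = FALSE] + sqrt(1 - rho) * e
    if (config$n_informative > 0 && config$effect_size > 0) {
      shift <- outer(outcome == 1L, informative) * config$effect_size
      z <- z + shift
    }

    sr <- config$feature_scale_range
    sds <- exp(stats::runif(p, log(sr[1]), log(sr[2])))
    mus <- stats::runif(p, -5, 5) * sds
    values <- sweep(sweep(z, 2, sds, `*`), 2, mus, `+`)
    colnames(values) <- sprintf("feat_%04d", seq_len(p))

    feature_table(values, outcome, informative_truth = informative)
  })
}
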