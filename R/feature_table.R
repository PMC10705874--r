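#' Construct a feature table
#'
#' A `feature_table` is the central container of the package: a numeric
#' matrix of samples (lesions) by named continuous features, a binary outcome
#' per sample (1 = clinically significant, 0 = non-significant), and a
#' per-feature provenance flag distinguishing real radiomics features from
#' injected random features. Synthetic tables additionally carry a
#' ground-truth flag marking which features were generated with a true
#' association to the outcome.
#'
#' @param values Numeric matrix, `n_samples x n_features`, with unique column
#'   names. Row names, if present, are used as sample identifiers.
#' @param outcome Vector of 0/1 (or coercible logical) of length `nrow(values)`.
#'   Both classes must be present.
#' @param sample_ids Optional character vector of sample identifiers; defaults
#'   to row names or `sample_0001...`.
#' @param provenance Character vector per feature, each `"real"` or
#'   `"random"`; defaults to all `"real"`.
#' @param informative_truth Optional logical vector per feature flagging the
#'   features generated with a true outcome association (synthetic tables
#'   only).
#' @return An object of class `feature_table`.
#' @seealso [generate_table()], [read_feature_table()], [write_feature_table()]
#' @export
feature_table <- function(values, outcome, sample_ids = NULL,
                          provenance = NULL, informative_truth = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(colnames(values))) {
    stop("`values` must have column (feature) names", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("feature names must be unique", call. = FALSE)
  }
  outcome <- as.integer(outcome)
  if (length(outcome) != nrow(values)) {
    stop("`outcome` length must equal the number of rows", call. = FALSE)
  }
  if (!all(outcome %in% c(0L, 1L))) {
    stop("`outcome` must be binary (0/1)", call. = FALSE)
  }
  if (length(unique(outcome)) < 2L) {
    stop("`outcome` must contain both classes", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) {
      sample_ids <- sprintf("sample_%04d", seq_len(nrow(values)))
    }
  }
  if (length(sample_ids) != nrow(values) || anyDuplicated(sample_ids)) {
    stop("`sample_ids` must be unique and match the number of rows",
         call. = FALSE)
  }
  if (is.null(provenance)) {
    provenance <- rep("real", ncol(values))
  }
  if (length(provenance) != ncol(values) ||
      !all(provenance %in% c("real", "random"))) {
    stop("`provenance` must be 'real'/'random' per feature", call. = FALSE)
  }
  if (!is.null(informative_truth)) {
    if (length(informative_truth) != ncol(values) ||
        !is.logical(informative_truth)) {
      stop("`informative_truth` must be logical per feature", call. = FALSE)
    }
  }
  rownames(values) <- sample_ids
  names(provenance) <- colnames(values)
  if (!is.null(informative_truth)) names(informative_truth) <- colnames(values)
  structure(
    list(values = values, outcome = outcome, sample_ids = sample_ids,
         provenance = provenance, informative_truth = informative_truth),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  n_rand <- sum(x$provenance == "random")
  cat(sprintf(
    "<feature_table> %d samples x %d features (%d real, %d random)\n",
    nrow(x$values), ncol(x$values), ncol(x$values) - n_rand, n_rand))
  cat(sprintf("  outcome: %d positive / %d negative\n",
              sum(x$outcome == 1L), sum(x$outcome == 0L)))
  if (!is.null(x$informative_truth)) {
    cat(sprintf("  ground truth: %d informative features\n",
                sum(x$informative_truth)))
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Feature names of a table
#' @param table A [feature_table()].
#' @param provenance Optional filter: `"real"` or `"random"`.
#' @return Character vector of feature names.
#' @export
feature_names <- function(table, provenance = NULL) {
  stopifnot(inherits(table, "feature_table"))
  nm <- colnames(table$values)
  if (!is.null(provenance)) nm <- nm[table$provenance == provenance]
  nm
}

#' Subset a feature table by samples and/or features
#'
#' @param table A [feature_table()].
#' @param samples Row indices, logical mask, or sample ids; `NULL` keeps all.
#' @param features Feature names or indices; `NULL` keeps all.
#' @return A new `feature_table`. Subsetting rows may yield a single-class
#'   outcome only when `allow_single_class = TRUE` (used internally for
#'   degenerate folds).
#' @param allow_single_class Permit subsets where one outcome class is absent.
#' @export
subset_table <- function(table, samples = NULL, features = NULL,
                         allow_single_class = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  v <- table$values
  prov <- table$provenance
  info <- table$informative_truth
  outc <- table$outcome
  ids <- table$sample_ids
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, ids)
    v <- v[samples, , drop = FALSE]
    outc <- outc[samples]
    ids <- ids[samples]
  }
  if (!is.null(features)) {
    v <- v[, features, drop = FALSE]
    prov <- prov[colnames(v)]
    if (!is.null(info)) info <- info[colnames(v)]
  }
  if (allow_single_class && length(unique(outc)) < 2L) {
    # bypass the constructor's both-classes invariant for internal fold work
    out <- structure(
      list(values = v, outcome = outc, sample_ids = ids,
           provenance = prov, informative_truth = info),
      class = "feature_table")
    return(out)
  }
  feature_table(v, outc, sample_ids = ids, provenance = prov,
                informative_truth = info)
}

#' Write a feature table to CSV with a JSON sidecar
#'
#' The CSV holds one header row of feature names plus a final `outcome`
#' column. Feature provenance, ground-truth flags and any extra metadata go
#' to `<path>.json` so that augmented tables round-trip losslessly.
#'
#' @param table A [feature_table()].
#' @param path Output CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @param metadata Optional named list stored verbatim in the sidecar
#'   (e.g. injection ratio, seeds, template assignments).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, metadata = NULL) {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table$values)
  df$outcome <- table$outcome
  utils::write.csv(cbind(sample_id = table$sample_ids, df), path,
                   row.names = FALSE)
  sidecar <- list(
    provenance = as.list(table$provenance),
    informative_truth = if (is.null(table$informative_truth)) NULL else
      as.list(table$informative_truth),
    metadata = metadata
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Accepts both the package's own CSV + JSON-sidecar format and plain feature
#' CSVs (such as public radiomics tables) with a named outcome column. All
#' feature columns must be numeric.
#'
#' @param path CSV path.
#' @param outcome_column Name of the binary outcome column (default `"outcome"`).
#' @param id_column Optional name of a sample-id column (default
#'   `"sample_id"` if present).
#' @return A [feature_table()]; provenance and ground truth are restored from
#'   `paste0(path, ".json")` when that sidecar exists.
#' @export
read_feature_table <- function(path, outcome_column = "outcome",
                               id_column = "sample_id") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!outcome_column %in% names(df)) {
    stop(sprintf("outcome column '%s' not found in %s", outcome_column, path),
         call. = FALSE)
  }
  outcome <- df[[outcome_column]]
  df[[outcome_column]] <- NULL
  ids <- NULL
  if (!is.null(id_column) && id_column %in% names(df)) {
    ids <- as.character(df[[id_column]])
    df[[id_column]] <- NULL
  }
  non_num <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(non_num) > 0L) {
    stop(sprintf("non-numeric feature columns: %s",
                 paste(non_num, collapse = ", ")), call. = FALSE)
  }
  values <- as.matrix(df)
  prov <- NULL
  info <- NULL
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path)
    if (!is.null(sc$provenance)) {
      prov <- unlist(sc$provenance)[colnames(values)]
    }
    if (!is.null(sc$informative_truth)) {
      info <- as.logical(unlist(sc$informative_truth)[colnames(values)])
    }
  }
  feature_table(values, outcome, sample_ids = ids, provenance = prov,
                informative_truth = info)
}
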