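#' Preprocessing configuration
#'
#' Defaults follow common single-cell practice: the 3000 most variable
#' genes, up to 50,000 most variable peaks, library-size scaling to 1e4
#' and a pseudocount of 1 for the centered log-ratio transform.
#'
#' @param n_hvg number of highly variable genes to keep.
#' @param n_top_peaks number of top-variance peaks to keep.
#' @param rna_target_sum per-spot library-size target after scaling.
#' @param pseudocount pseudocount for the CLR transform.
#' @return a list of class `preprocess_config`.
#' @export
preprocess_config <- function(n_hvg = 3000, n_top_peaks = 50000,
                              rna_target_sum = 1e4, pseudocount = 1) {
  stopifnot(n_hvg > 0, n_top_peaks > 0, rna_target_sum > 0, pseudocount > 0)
  structure(list(n_hvg = n_hvg, n_top_peaks = n_top_peaks,
                 rna_target_sum = rna_target_sum, pseudocount = pseudocount),
            class = "preprocess_config")
}

as_dense <- function(v) as.matrix(v)

col_vars <- function(m) {
  # column variances of a dense matrix
  n <- nrow(m)
  if (n < 2) return(rep(0, ncol(m)))
  mu <- colMeans(m)
  (colSums(m^2) - n * mu^2) / (n - 1)
}

check_nonzero_rows <- function(m, spot_ids, what) {
  rs <- rowSums(m)
  if (any(rs <= 0))
    stop("cannot normalize ", what, ": all-zero counts for spot(s) ",
         paste(utils::head(spot_ids[rs <= 0], 5), collapse = ", "))
  rs
}

# Deterministic top-k by value, ties broken by original column index.
top_k_keep_order <- function(values, k) {
  k <- min(k, length(values))
  ord <- order(-values, seq_along(values))
  sort(ord[seq_len(k)])
}

#' Normalize RNA counts
#'
#' Scales each spot to `rna_target_sum` total counts, applies `log1p`, then
#' keeps the `n_hvg` genes with largest variance of the transformed values
#' (ties broken by original column index), preserving column order.
#'
#' @param matrix a raw-count [modality_matrix()] (`rna`).
#' @param cfg a [preprocess_config()].
#' @return a preprocessed [modality_matrix()].
#' @export
preprocess_rna <- function(matrix, cfg = preprocess_config()) {
  stopifnot(inherits(matrix, "modality_matrix"))
  if (matrix$layer != "raw") stop("expected raw counts")
  x <- as_dense(matrix$values)
  if (any(x < 0)) stop("counts must be nonnegative")
  rs <- check_nonzero_rows(x, matrix$spot_ids, "RNA")
  x <- log1p(x / rs * cfg$rna_target_sum)
  keep <- top_k_keep_order(col_vars(x), cfg$n_hvg)
  modality_matrix(x[, keep, drop = FALSE], matrix$spot_ids,
                  matrix$feature_ids[keep], matrix$modality, "preprocessed")
}

#' TF-IDF transform of ATAC peak counts
#'
#' Keeps the `n_top_peaks` peaks with largest raw-count variance, computes
#' TF-IDF with `TF_ij = x_ij / rowsum_i` and the log-smoothed
#' `IDF_j = ln(1 + N / (1 + df_j))` where `df_j` counts spots with peak `j`
#' open, then scales each spot of the TF-IDF matrix to `rna_target_sum` and
#' applies `log1p`.
#'
#' @inheritParams preprocess_rna
#' @return a preprocessed [modality_matrix()].
#' @export
preprocess_atac <- function(matrix, cfg = preprocess_config()) {
  stopifnot(inherits(matrix, "modality_matrix"))
  if (matrix$layer != "raw") stop("expected raw counts")
  x <- as_dense(matrix$values)
  if (any(x < 0)) stop("counts must be nonnegative")
  keep <- top_k_keep_order(col_vars(x), cfg$n_top_peaks)
  x <- x[, keep, drop = FALSE]
  rs <- check_nonzero_rows(x, matrix$spot_ids, "ATAC")
  tf <- x / rs
  df <- colSums(x > 0)
  idf <- log(1 + nrow(x) / (1 + df))
  ti <- sweep(tf, 2, idf, `*`)
  trs <- rowSums(ti)
  ti <- log1p(ti / trs * cfg$rna_target_sum)
  modality_matrix(ti, matrix$spot_ids, matrix$feature_ids[keep],
                  matrix$modality, "preprocessed")
}

#' Centered log-ratio transform of protein (ADT) counts
#'
#' Per spot, `y_j = ln(x_j + pseudocount) - mean_j ln(x_j + pseudocount)`.
#'
#' @inheritParams preprocess_rna
#' @return a preprocessed [modality_matrix()].
#' @export
preprocess_protein <- function(matrix, cfg = preprocess_config()) {
  stopifnot(inherits(matrix, "modality_matrix"))
  if (matrix$layer != "raw") stop("expected raw counts")
  x <- as_dense(matrix$values)
  if (any(x < 0)) stop("counts must be nonnegative")
  lx <- log(x + cfg$pseudocount)
  y <- lx - rowMeans(lx)
  modality_matrix(y, matrix$spot_ids, matrix$feature_ids,
                  matrix$modality, "preprocessed")
}

#' Dispatch preprocessing on the modality tag
#' @inheritParams preprocess_rna
#' @return a preprocessed [modality_matrix()].
#' @export
preprocess_modality <- function(matrix, cfg = preprocess_config()) {
  switch(matrix$modality,
         rna = preprocess_rna(matrix, cfg),
         atac = preprocess_atac(matrix, cfg),
         protein = preprocess_protein(matrix, cfg),
         metabolite = preprocess_protein(matrix, cfg),
         stop("no preprocessing rule for modality ", matrix$modality))
}

#' Preprocess both modalities of a dataset
#' @param dataset a raw [spatial_multiome()] dataset.
#' @param cfg a [preprocess_config()].
#' @return the dataset with both matrices preprocessed (features possibly
#'   subset by variable-feature selection).
#' @export
preprocess_dataset <- function(dataset, cfg = preprocess_config()) {
  spatial_multiome(preprocess_modality(dataset$modality1, cfg),
                   preprocess_modality(dataset$modality2, cfg),
                   dataset$annotations, dataset$coords)
}
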