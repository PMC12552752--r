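#' Fuse the two per-modality embeddings
#'
#' The fused spot embedding is the elementwise average `(f + g) / 2`.
#'
#' @param f,g embedding matrices of equal shape (`N x d`).
#' @return fused matrix `Z`.
#' @export
fuse_embeddings <- function(f, g) {
  if (!all(dim(f) == dim(g))) stop("shape mismatch between f and g")
  (f + g) / 2
}

as_cluster_result <- function(labels, method, parameters, spot_ids = NULL) {
  labels <- as.integer(factor(labels)) - 1L  # contiguous codes from 0
  if (!is.null(spot_ids)) names(labels) <- spot_ids
  structure(list(labels = labels, method = method, parameters = parameters),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s: %d spots, %d clusters\n",
              x$method, length(x$labels), length(unique(x$labels))))
  invisible(x)
}

#' Louvain clustering of embeddings
#'
#' Community detection on the union-symmetrized k-nearest-neighbor graph
#' (Euclidean) of the embeddings.
#'
#' @param Z embedding matrix (`N x d`), spot ids as row names.
#' @param k_neighbors neighbors per spot (must be `< N`).
#' @param resolution Louvain resolution parameter. The default (0.1) is
#'   tuned to domain-scale structure - a handful of spatial domains per
#'   tissue section; raise it to resolve finer substructure.
#' @param seed RNG seed (Louvain is stochastic).
#' @return a `cluster_result` with 0-based contiguous labels.
#' @export
cluster_louvain <- function(Z, k_neighbors = 15, resolution = 0.1, seed = 0) {
  n <- nrow(Z)
  if (k_neighbors >= n) stop("k_neighbors must be smaller than the number of spots")
  d <- as.matrix(stats::dist(Z))
  diag(d) <- Inf
  nb <- apply(d, 1, function(row) order(row)[seq_len(k_neighbors)])
  ii <- rep(seq_len(n), each = k_neighbors)
  jj <- as.vector(nb)
  el <- unique(cbind(pmin(ii, jj), pmax(ii, jj)))  # union-symmetrized
  gr <- igraph::graph_from_edgelist(el, directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0, n - igraph::vcount(gr)))
  set.seed(seed)
  cl <- igraph::cluster_louvain(gr, resolution = resolution)
  as_cluster_result(igraph::membership(cl), "louvain",
                    list(k_neighbors = k_neighbors, resolution = resolution,
                         seed = seed),
                    rownames(Z))
}

#' Gaussian-mixture (model-based) clustering of embeddings
#'
#' K-component Gaussian mixture with full covariances fitted by
#' `mclust::Mclust`; spots are hard-assigned to the maximal-posterior
#' component.
#'
#' @param Z embedding matrix.
#' @param K number of components (>= 2).
#' @param seed RNG seed.
#' @return a `cluster_result`.
#' @export
cluster_gmm <- function(Z, K, seed = 0) {
  if (K < 2) stop("K must be >= 2")
  if (K > nrow(Z)) stop("K exceeds the number of spots")
  set.seed(seed)
  mclustBIC <- mclust::mclustBIC  # Mclust looks this up in the caller
  fit <- mclust::Mclust(Z, G = K, modelNames = "VVV", verbose = FALSE)
  if (is.null(fit)) fit <- mclust::Mclust(Z, G = K, verbose = FALSE)
  as_cluster_result(fit$classification, "gmm",
                    list(K = K, seed = seed), rownames(Z))
}

#' Per-cluster differential features by Wilcoxon rank-sum test
#'
#' For every cluster, tests each feature in-cluster vs rest (two-sided),
#' adjusts p-values by Benjamini-Hochberg across features within the
#' cluster, and reports the difference of means of the preprocessed
#' values as effect size.
#'
#' @param matrix preprocessed [modality_matrix()] (or plain matrix).
#' @param labels per-spot cluster labels.
#' @return data.frame `cluster`, `feature`, `stat`, `p`, `p_adj`,
#'   `effect`, sorted within cluster by adjusted p then decreasing effect.
#' @export
rank_deg_wilcoxon <- function(matrix, labels) {
  x <- if (inherits(matrix, "modality_matrix")) as.matrix(matrix$values) else as.matrix(matrix)
  labels <- as.vector(labels)
  if (length(labels) != nrow(x)) stop("labels do not match the spots")
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 clusters")
  if (any(tab < 2))
    stop("singleton cluster: ", names(tab)[tab < 2][1])
  res <- list()
  for (cl in names(tab)) {
    inn <- labels == cl
    stats_p <- apply(x, 2, function(v) {
      wt <- suppressWarnings(stats::wilcox.test(v[inn], v[!inn]))
      p <- wt$p.value
      if (is.nan(p)) p <- 1  # fully tied feature: no evidence
      c(wt$statistic, p)
    })
    effect <- colMeans(x[inn, , drop = FALSE]) - colMeans(x[!inn, , drop = FALSE])
    df <- data.frame(cluster = cl, feature = colnames(x),
                     stat = stats_p[1, ], p = stats_p[2, ],
                     p_adj = stats::p.adjust(stats_p[2, ], "BH"),
                     effect = effect, stringsAsFactors = FALSE)
    res[[cl]] <- df[order(df$p_adj, -df$effect), , drop = FALSE]
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

comb2 <- function(v) v * (v - 1) / 2

entropy_counts <- function(cnt) {
  p <- cnt[cnt > 0] / sum(cnt)
  -sum(p * log(p))
}

# Expected mutual information under the permutation model (hypergeometric),
# used by the adjusted mutual information.
expected_mi <- function(a, b, n) {
  emi <- 0
  for (ai in a) for (bj in b) {
    lo <- max(1, ai + bj - n)
    hi <- min(ai, bj)
    if (hi < lo) next
    nij <- lo:hi
    lp <- lchoose(bj, nij) + lchoose(n - bj, ai - nij) - lchoose(n, ai)
    emi <- emi + sum(exp(lp) * nij / n * log(n * nij / (ai * bj)))
  }
  emi
}

#' Clustering agreement metrics
#'
#' Computes the standard pair-counting and information-theoretic
#' agreement measures between a clustering and reference labels from
#' their contingency table: Rand index, adjusted Rand index, adjusted and
#' normalized mutual information (arithmetic normalization), homogeneity,
#' completeness, V-measure, and the Fowlkes-Mallows index.
#'
#' @param labels predicted cluster labels.
#' @param truth reference labels of equal length.
#' @return named list of metric values.
#' @export
clustering_metrics <- function(labels, truth) {
  if (length(labels) != length(truth)) stop("length mismatch")
  n <- length(labels)
  ct <- table(truth, labels)
  a <- rowSums(ct); b <- colSums(ct)
  tp <- sum(comb2(ct))
  sa <- sum(comb2(a)); sb <- sum(comb2(b))
  tot <- comb2(n)
  ri <- (tot + 2 * tp - sa - sb) / tot
  exp_tp <- sa * sb / tot
  max_tp <- (sa + sb) / 2
  ari <- if (max_tp == exp_tp) 1 else (tp - exp_tp) / (max_tp - exp_tp)
  fmi <- if (sa == 0 || sb == 0) 0 else tp / sqrt(sa * sb)
  hu <- entropy_counts(a); hv <- entropy_counts(b)
  nz <- ct > 0
  mi <- sum((ct[nz] / n) * log(n * ct[nz] / (a[row(ct)[nz]] * b[col(ct)[nz]])))
  nmi <- if (hu == 0 && hv == 0) 1 else if (mi == 0) 0 else mi / ((hu + hv) / 2)
  emi <- expected_mi(as.numeric(a), as.numeric(b), n)
  denom <- (hu + hv) / 2 - emi
  ami <- if (abs(denom) < .Machine$double.eps) 1 else (mi - emi) / denom
  # conditional entropies from the contingency table
  h_truth_given <- hu - mi   # H(truth | labels)
  h_lab_given <- hv - mi     # H(labels | truth)
  homog <- if (hu == 0) 1 else 1 - h_truth_given / hu
  compl <- if (hv == 0) 1 else 1 - h_lab_given / hv
  vm <- if (homog + compl == 0) 0 else 2 * homog * compl / (homog + compl)
  list(RI = ri, ARI = ari, AMI = ami, NMI = nmi, homogeneity = homog,
       completeness = compl, v_measure = vm, FMI = fmi)
}

icc1_feature <- function(v, labels) {
  gm <- tapply(v, labels, mean)
  gn <- tapply(v, labels, length)
  k <- length(gm)
  n <- length(v)
  kbar <- mean(gn)
  ssb <- sum(gn * (gm - mean(v))^2)
  ssw <- sum((v - gm[as.character(labels)])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  if (msb + (kbar - 1) * msw == 0) return(NA_real_)
  (msb - msw) / (msb + (kbar - 1) * msw)
}

#' Intraclass correlation of features within clusters
#'
#' Per feature, the one-way random-effects ICC(1)
#' `(MSB - MSW) / (MSB + (kbar - 1) MSW)` with clusters as groups and
#' `kbar` the mean group size; the per-modality score is the mean over
#' features, clipped to `[-1, 1]`. Features with no variance contribute 0
#' (with a warning when all are degenerate).
#'
#' @param matrix preprocessed values ([modality_matrix()] or matrix).
#' @param labels per-spot cluster labels (>= 2 clusters with >= 2
#'   members).
#' @return list with `per_feature` ICCs and the summary `icc`.
#' @export
icc_score <- function(matrix, labels) {
  x <- if (inherits(matrix, "modality_matrix")) as.matrix(matrix$values) else as.matrix(matrix)
  labels <- as.vector(labels)
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2))
    stop("ICC needs >= 2 clusters with >= 2 members each")
  per <- apply(x, 2, icc1_feature, labels = labels)
  if (all(is.na(per))) {
    warning("all features have degenerate variance; ICC set to 0")
    per[] <- 0
  }
  per[is.na(per)] <- 0
  per <- pmin(pmax(per, -1), 1)
  list(per_feature = per, icc = mean(per))
}

#' Combined ICC across the two modalities
#'
#' Unweighted mean of the two per-modality ICC summaries.
#'
#' @param matrix1,matrix2 preprocessed values of the two modalities.
#' @param labels per-spot cluster labels.
#' @return list with `icc1`, `icc2` and `combined`.
#' @export
icc_combined <- function(matrix1, matrix2, labels) {
  i1 <- icc_score(matrix1, labels)$icc
  i2 <- icc_score(matrix2, labels)$icc
  list(icc1 = i1, icc2 = i2, combined = (i1 + i2) / 2)
}
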