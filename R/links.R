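#' Extract peak-gene attention scores from a trained model
#'
#' For every peak-gene edge of the feature graph, returns the attention
#' weight the peak's normalized neighborhood (its connected genes plus its
#' self-loop) assigns to the gene, recomputed from the final parameters.
#' The peak-side normalization is the operational definition of the
#' regulatory score.
#'
#' @param state a trained [init_model()] state.
#' @param outputs the [model_forward()] outputs of the trained state.
#' @param graph the [build_feature_graph()] used in training.
#' @return data.frame with `peak_id`, `gene_id`, `chrom`, `start`, `end`,
#'   `dist`, `att`, sorted by (`peak_id`, `gene_id`).
#' @export
extract_pair_scores <- function(state, outputs, graph) {
  if (!isTRUE(state$trained)) stop("model state is untrained")
  att <- outputs$catt
  # cross-modality pairs targeted at the peak/protein side, self excluded
  src_kind <- if (graph$mode == "genomic") "peak" else
    if (graph$mode == "coding") "protein" else "metabolite"
  sel <- graph$kind[att$ti] == src_kind & graph$kind[att$si] == "gene"
  tb <- data.frame(peak_id = graph$nodes[att$ti[sel]],
                   gene_id = graph$nodes[att$si[sel]],
                   att = att$att[sel], stringsAsFactors = FALSE)
  key_e <- paste(graph$edges$feature1, graph$edges$feature2)
  idx <- match(paste(tb$peak_id, tb$gene_id), key_e)
  tb$dist <- graph$edges$dist[idx]
  tb <- tb[order(tb$peak_id, tb$gene_id), , drop = FALSE]
  rownames(tb) <- NULL
  tb[, c("peak_id", "gene_id", "dist", "att")]
}

#' Rescale attention values linearly onto the unit interval
#'
#' Minimum maps to 0, maximum to 1; order-preserving.
#'
#' @param att numeric vector of non-self attention values (>= 2 distinct
#'   values).
#' @return rescaled scores.
#' @export
rescale_unit_interval <- function(att) {
  if (length(att) < 2) stop("need at least 2 attention values")
  rng <- range(att)
  if (rng[1] == rng[2])
    stop("attention values are constant; rescaling is degenerate")
  (att - rng[1]) / (rng[2] - rng[1])
}

kmeanspp_1d <- function(x, k = 2) {
  # k-means++ seeding followed by Lloyd iterations on 1-D data
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1)]
  for (j in 2:k) {
    d2 <- (x - centers[1])^2
    if (j > 2) for (h in 2:(j - 1)) d2 <- pmin(d2, (x - centers[h])^2)
    if (sum(d2) == 0) centers[j] <- x[sample.int(length(x), 1)]
    else centers[j] <- x[sample.int(length(x), 1, prob = d2)]
  }
  cl <- stats::kmeans(x, centers = matrix(centers, ncol = 1))
  cl
}

#' Two-component Gaussian mixture threshold
#'
#' Fits a two-component univariate Gaussian mixture by EM (k-means++
#' initialization with the given seed) and returns the density
#' intersection point between the two means: the value at which the
#' posterior probability of belonging to either component is equal, found
#' by bracketed root search at tolerance 1e-6.
#'
#' @param scores rescaled attention scores.
#' @param seed RNG seed for the EM initialization.
#' @param min_scores minimum number of scores required (default 50).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return list with `theta`, `means`, `sds`, `weights` (means ordered
#'   increasingly), EM `iterations` and `loglik`.
#' @export
gmm_threshold <- function(scores, seed = 0, min_scores = 50,
                          max_iter = 500, tol = 1e-8) {
  x <- as.numeric(scores)
  if (length(x) < min_scores)
    stop("need at least ", min_scores, " scores, got ", length(x))
  set.seed(seed)
  km <- kmeanspp_1d(x, 2)
  mu <- as.numeric(km$centers)
  pi_ <- as.numeric(table(factor(km$cluster, levels = 1:2))) / length(x)
  s2 <- vapply(1:2, function(j) {
    v <- stats::var(x[km$cluster == j])
    if (!is.finite(v) || v < 1e-12) 1e-12 else v
  }, numeric(1))
  ll_old <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    d1 <- pi_[1] * stats::dnorm(x, mu[1], sqrt(s2[1]))
    d2 <- pi_[2] * stats::dnorm(x, mu[2], sqrt(s2[2]))
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    if (it >= max_iter)
      stop("EM did not converge after ", it, " iterations")
    ll_old <- ll
    n1 <- sum(r); n2 <- length(x) - n1
    pi_ <- c(n1, n2) / length(x)
    mu <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    s2 <- c(sum(r * (x - mu[1])^2) / n1,
            sum((1 - r) * (x - mu[2])^2) / n2)
    s2 <- pmax(s2, 1e-12)
  }
  ord <- order(mu)
  mu <- mu[ord]; s2 <- s2[ord]; pi_ <- pi_[ord]
  h <- function(v) pi_[1] * stats::dnorm(v, mu[1], sqrt(s2[1])) -
    pi_[2] * stats::dnorm(v, mu[2], sqrt(s2[2]))
  lo <- mu[1] + 1e-9 * max(1, abs(mu[1]))
  hi <- mu[2] - 1e-9 * max(1, abs(mu[2]))
  if (!(hi > lo) || h(lo) * h(hi) > 0)
    stop("no density intersection between the component means ",
         sprintf("(%.4f, %.4f)", mu[1], mu[2]),
         "; the score distribution may not be bimodal - ",
         "supply a manual threshold")
  theta <- stats::uniroot(h, c(lo, hi), tol = 1e-6)$root
  list(theta = theta, means = mu, sds = sqrt(s2), weights = pi_,
       iterations = it, loglik = ll)
}

#' Call regulatory links at a threshold
#'
#' @param table output of [extract_pair_scores()] augmented with a
#'   `score` column (see [rescale_unit_interval()]), or a table to which
#'   the score is added here.
#' @param theta threshold in `[0, 1]`.
#' @return the table with `score` and logical `called` columns, sorted by
#'   descending score (ties by peak then gene id); `theta` and the
#'   mixture, when supplied, travel as attributes.
#' @export
call_links <- function(table, theta) {
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  if (is.null(table$score)) table$score <- rescale_unit_interval(table$att)
  table$called <- table$score >= theta
  ord <- order(-table$score, table$peak_id, table$gene_id)
  out <- table[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "theta") <- theta
  out
}

#' Area under the ROC curve by the rank statistic
#'
#' Tie-corrected Mann-Whitney formulation; equals the proportion of
#' concordant positive-negative pairs with ties counted as 1/2.
#'
#' @param scores numeric predictions.
#' @param labels logical/0-1 ground truth.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("need both positive and negative labels")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Points of the empirical ROC curve (one per distinct score threshold),
#' suitable for export alongside the AUROC.
#'
#' @param scores numeric predictions.
#' @param labels logical/0-1 ground truth.
#' @return data.frame `threshold`, `fpr`, `tpr`, ordered by descending
#'   threshold.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("need both positive and negative labels")
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores >= t & labels) / n1, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & !labels) / n0, numeric(1))
  data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Evaluate called links against an external benchmark
#'
#' The benchmark table provides per-gene supported regions: either point
#' loci (`mode = "eqtl"`: columns `gene_id`, `chrom`, `pos`; a pair is
#' supported when a locus associated with the gene falls inside the peak
#' interval) or intervals (`mode = "enhancer"`: columns `gene_id`,
#' `chrom`, `start`, `end`; supported when the peak overlaps a region
#' annotated to the gene). Evaluation is restricted to genes present in
#' the benchmark.
#'
#' @param table link table with `peak_id`, `gene_id`, `score` and peak
#'   coordinates `chrom`, `start`, `end`.
#' @param benchmark benchmark data.frame as above.
#' @param mode `"eqtl"` or `"enhancer"`.
#' @return list with the restricted `table` (plus logical `supported`)
#'   and the `auroc` of score vs support.
#' @export
evaluate_links <- function(table, benchmark, mode = c("eqtl", "enhancer")) {
  mode <- match.arg(mode)
  need <- c("peak_id", "gene_id", "score", "chrom", "start", "end")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("link table lacks columns: ", paste(miss, collapse = ", "))
  tb <- table[table$gene_id %in% benchmark$gene_id, , drop = FALSE]
  if (!nrow(tb)) stop("no link gene is present in the benchmark")
  if (mode == "eqtl") {
    bm <- GenomicRanges::GRanges(benchmark$chrom,
                                 IRanges::IRanges(benchmark$pos + 1, width = 1))
  } else {
    bm <- GenomicRanges::GRanges(benchmark$chrom,
                                 IRanges::IRanges(benchmark$start + 1, benchmark$end))
  }
  pk <- GenomicRanges::GRanges(tb$chrom, IRanges::IRanges(tb$start + 1, tb$end))
  hits <- GenomicRanges::findOverlaps(pk, bm)
  same_gene <- tb$gene_id[S4Vectors::queryHits(hits)] ==
    benchmark$gene_id[S4Vectors::subjectHits(hits)]
  tb$supported <- FALSE
  tb$supported[unique(S4Vectors::queryHits(hits)[same_gene])] <- TRUE
  if (all(tb$supported) || !any(tb$supported))
    stop("benchmark yields no ", if (all(tb$supported)) "negative" else "positive",
         " pairs; AUROC undefined")
  list(table = tb, auroc = auroc(tb$score, tb$supported))
}

#' Full attention-to-links procedure
#'
#' Pools the peak-targeted cross-modality attentions (self-attention
#' excluded), rescales them onto `[0, 1]`, fits the two-component mixture
#' threshold and calls links.
#'
#' @param state,outputs,graph see [extract_pair_scores()].
#' @param annotations the [feature_annotation()] table (supplies peak
#'   coordinates for the output table).
#' @param seed seed for the mixture fit.
#' @return the called link table (see [call_links()]) with the mixture
#'   stored in `attr(, "gmm")`.
#' @export
infer_links <- function(state, outputs, graph, annotations, seed = 0) {
  tb <- extract_pair_scores(state, outputs, graph)
  ai <- match(tb$peak_id, annotations$feature_id)
  tb$chrom <- annotations$chrom[ai]
  tb$start <- annotations$start[ai]
  tb$end <- annotations$end[ai]
  tb$score <- rescale_unit_interval(tb$att)
  gmm <- gmm_threshold(tb$score, seed = seed)
  out <- call_links(tb, gmm$theta)
  attr(out, "gmm") <- gmm
  out
}
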