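# Small in-code fixtures shared across test files.

tiny_dataset <- function(seed = 1, grid = c(3, 4), n_genes = 6,
                         decoys = 1, domains = 2) {
  simulate_tissue(sim_config(grid = grid, n_domains = domains,
                             n_genes = n_genes,
                             decoy_peaks_per_gene = decoys, seed = seed))
}

tiny_pipeline_input <- function(seed = 1) {
  sim <- tiny_dataset(seed = seed)
  pre <- preprocess_dataset(sim$dataset, preprocess_config(n_hvg = 1000))
  fg <- build_feature_graph(reorder_annotation(pre), mode = "genomic")
  sg <- build_spatial_graph(pre$coords, layout = "grid4")
  list(sim = sim, pre = pre, fg = fg, sg = sg)
}

# annotation rows in concatenated-feature order (modality1 then modality2)
reorder_annotation <- function(dataset) {
  feats <- c(dataset$modality1$feature_ids, dataset$modality2$feature_ids)
  ann <- dataset$annotations[match(feats, dataset$annotations$feature_id), ]
  class(ann) <- c("feature_annotation", "data.frame")
  ann
}

small_model <- function(inp, hidden = c(5, 3), seed = 7, randomize_att = TRUE) {
  n <- nrow(inp$pre$modality1$values)
  st <- init_model(n, ncol(inp$pre$modality1$values),
                   ncol(inp$pre$modality2$values),
                   hidden = hidden, d_proj = hidden[2], seed = seed)
  if (randomize_att) {
    set.seed(seed + 1)
    for (nm in c("v1", "v2", "vself_1", "vnei_1", "vself_2", "vnei_2"))
      st$params[[nm]] <- stats::rnorm(length(st$params[[nm]]), sd = 0.3)
  }
  st
}

# brute-force pair-counting Rand/ARI oracle
ari_bruteforce <- function(labels, truth) {
  n <- length(labels)
  same_l <- outer(labels, labels, "==")[upper.tri(diag(n))]
  same_t <- outer(truth, truth, "==")[upper.tri(diag(n))]
  a <- sum(same_l & same_t); b <- sum(!same_l & !same_t)
  c_ <- sum(same_l & !same_t); d <- sum(!same_l & same_t)
  tot <- a + b + c_ + d
  ri <- (a + b) / tot
  # chance-corrected via expected index
  exp_a <- (a + c_) * (a + d) / tot
  max_a <- ((a + c_) + (a + d)) / 2
  if (max_a == exp_a) return(list(RI = ri, ARI = 1))
  list(RI = ri, ARI = (a - exp_a) / (max_a - exp_a))
}

# exhaustive pairwise-comparison AUROC oracle
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# exact two-sided rank-sum p-value by enumeration of all group assignments
wilcox_exact_p <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  v <- c(x, y)
  r <- rank(v)
  obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(n, nx)
  stats_all <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- nx * (n + 1) / 2
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-9)
}
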