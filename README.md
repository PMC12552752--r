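# spagate

Joint embedding and cis-regulatory inference for **spatial multi-omics**
data — paired spot-by-feature measurements of two molecular layers (RNA +
ATAC peaks, or RNA + protein ADTs) from the same tissue section — built
around a **two-level graph attention autoencoder**.

* **Level 1 (cross-modality).** Features of both modalities exchange
  information along a connectivity graph. For peak–gene pairs the
  attention combines a genomic-distance prior
  `A_fg = exp(((d_fg + w)/w)^-0.75)` (bandwidth `w = 400` bp, pairs
  within 150 kb of the TSS) with a data-driven coefficient
  `e_fg = sigmoid(v1'X_f + v2'X_g)`, normalized over each feature's
  neighborhood including its self-loop. The attention a peak pays a gene
  **is** the regulatory score.
* **Level 2 (within-modality).** Per modality, a two-layer graph
  attention encoder (`d -> 512 -> 30`) aggregates over the spot
  adjacency graph (grid, hexagonal, or kNN), encouraging neighboring
  spots to share embeddings. Decoders mirror the encoders with
  transposed projections and tied attentions.
* **Training.** Full-batch Adam (lr `1e-4`, weight decay `1e-4`, 1000
  iterations) on `sum_i ||X_i - Xhat_i||_2` (both modalities) plus a
  symmetric CLIP contrastive loss aligning the two per-spot embeddings.
  Gradients are hand-derived reverse-mode and finite-difference checked.
* **Link calling.** Peak-side attentions are rescaled to [0, 1]; a
  two-component Gaussian mixture is fitted and the density-intersection
  point between the component means becomes the calling threshold.
* **Downstream.** Fused embeddings `(f + g)/2`, Louvain or
  Gaussian-mixture clustering, Wilcoxon markers with BH adjustment,
  clustering agreement metrics (ARI & co.), intraclass correlation.
* **Synthetic tissue generator.** A layered-tissue simulator with known
  domains, planted distance-bounded peak–gene links and decoy peaks
  makes every stage testable without external data.

## Worked example

```r
library(spagate)

sim <- simulate_tissue(sim_config(seed = 0))      # 400 spots, 150 genes, 450 peaks
pre <- preprocess_dataset(sim$dataset)            # depth/log RNA, TF-IDF ATAC
gs  <- dataset_graphs(pre)                        # peak-gene graph (150 kb prior)
                                                  # + rook-adjacency spot graph
fit <- train_model(pre, gs$fg, gs$sg, train_config(seed = 0))
tail(fit$trace, 1)
#>      iteration    total    recon     clip
#> 1000      1000 14345.29 14340.42 4.875043

emb <- fuse_embeddings(fit$outputs$f, fit$outputs$g)
rownames(emb) <- pre$modality1$spot_ids
cl <- cluster_louvain(emb, seed = 0)
clustering_metrics(cl$labels, sim$truth$domains)$ARI
#> [1] 0.8886608

links <- infer_links(fit$state, fit$outputs, gs$fg, pre$annotations, seed = 0)
attr(links, "gmm")$theta
#> [1] 0.7540734
head(links[, c("peak_id", "gene_id", "dist", "score", "called")], 3)
#>     peak_id  gene_id  dist  score called
#> 1 peak_0095 gene_032  5842 1.0000   TRUE
#> 2 peak_0418 gene_140 12884 0.9647   TRUE
#> 3 peak_0291 gene_097 65042 0.9488   TRUE
```

The loss trace shows the optimization converging; the adjusted Rand
index of 0.89 against the simulated stripe domains says the fused
embeddings recover the tissue layout almost exactly (a Gaussian mixture
with the true domain count recovers it perfectly, ARI 1.0); `theta` is
the data-driven score cutoff separating the two modes of the rescaled
attention distribution, and the link table ranks every candidate
peak–gene pair by its attention score.

A staged command-line interface over the same functions is included:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/spagate.R", package="spagate"))')" \
    pipeline --out run1 --seed 0
```

runs simulate → preprocess → graphs → train → links → cluster →
evaluate and leaves TSV/JSON artifacts plus the resolved YAML
configuration in `run1/`.

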