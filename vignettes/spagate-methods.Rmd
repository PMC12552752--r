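---
title: "Methods: a two-level graph attention autoencoder for spatial multi-omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-level graph attention autoencoder for spatial multi-omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Spatial multi-omics assays measure two molecular layers — typically RNA
plus chromatin accessibility (ATAC peaks) or RNA plus surface proteins
(ADTs) — on the same spatially barcoded spots of a tissue section. Two
analysis goals are coupled: (i) embed the spots in a low-dimensional
space that respects both modalities and the tissue's spatial
organization, for spatial-domain clustering; and (ii) infer which
cross-modality feature pairs are functionally connected, above all which
accessible peaks regulate which nearby genes (cis-regulation).

`spagate` addresses both with a single model: a two-level graph
attention autoencoder whose *cross-modality* attention doubles as the
regulatory score.

## The model

Write the preprocessed matrices as $X_1 \in \mathbb{R}^{N\times p}$
(e.g. RNA) and $X_2 \in \mathbb{R}^{N\times q}$ (e.g. ATAC), and let
$X = [X_1\, X_2]$ with feature profiles $X_{(f)} \in \mathbb{R}^N$.

**Level 1 — cross-modality attention.** A feature connectivity graph
joins the two modalities: in genomic mode every peak–gene pair on the
same chromosome whose TSS distance is at most 150 kb is connected; in
coding mode a protein connects to the genes coding it. Each connection
carries a prior weight from the distance kernel

$$A_{fg} = \exp\!\Big(\big(\tfrac{d_{fg} + w}{w}\big)^{-0.75}\Big),
\qquad w = 400\ \mathrm{bp},$$

which equals $e$ at distance 0 and decays strictly towards (never
reaching) 1. Self-loops use $A_{ff} = A(d{=}0) = e$ in genomic mode so
that the prior treats a feature's own profile as its closest neighbor.
Raw attention coefficients are computed on the *unprojected* profiles,

$$e_{fg} = \sigma\big(v_1^\top X_{(f)} + v_2^\top X_{(g)}\big),$$

with trainable $v_1, v_2 \in \mathbb{R}^N$, and normalized in a
Bayesian-like fashion over each target's neighborhood including its
self-loop:

$$\mathrm{att}_{fg} =
\frac{A_{fg}\, e^{e_{fg}}}{\sum_{h \in \mathcal{N}_f \cup \{f\}} A_{fh}\, e^{e_{fh}}}.$$

The encoder output is the convex combination
$\bar X_{(f)} = \mathrm{ReLU}\big(\sum_g \mathrm{att}_{fg} X_{(g)}\big)$.
Including the self term in the normalization is a deliberate reading of
an ambiguity: without it, a peak connected to a single gene would
receive attention exactly 1 regardless of the data, the encoder update
would no longer be a convex combination, and the score would be
uninformative. With it, the self-loop competes with the neighbors and
the attention a peak pays its gene is exactly the quantity later used as
the regulatory score.

**Level 2 — within-modality spatial attention.** Per modality, a
two-layer encoder ($d_k \to 512 \to 30$) aggregates over the spot
adjacency graph (rook/queen grid, hexagonal lattice, or kNN; every spot
neighbors itself). Layer 1 is a graph attention layer with coefficients
$\sigma(v_{self}^\top W^1 \bar x_i + v_{nei}^\top W^1 \bar x_j)$
softmax-normalized over each spot's neighborhood, followed by ELU. Layer
2 is an *unweighted, unnormalized* neighbor sum through $W^2$ — kept
exactly in that form rather than a mean, with a mean variant available,
because the sum is the printed definition of the architecture this
package implements. The decoders mirror the encoders with transposed
projections and reused attentions; no decoder parameters exist anywhere
in the model state, which both regularizes and guarantees the tying
invariant testable by inspection.

**Losses.** Training minimizes the sum of a reconstruction term — the
sum over spots of per-spot Euclidean *norms* (not squared norms) of the
residuals in each modality — and a symmetric contrastive (CLIP) term
over cosine similarities of the projected embeddings
$f_i = M_1^\top \bar x^{(L)}_{1i}$, $g_i = M_2^\top \bar x^{(L)}_{2i}$,
scaled by $\exp(\mathrm{temp})$ with $\mathrm{temp}=1$ (the literal
$\exp(\cdot)$ scaling is intentional). The two terms are weighted 1:1 by
default; both weights are exposed because no trade-off coefficient is
prescribed. Optimization is full-batch Adam, learning rate $10^{-4}$,
weight decay $10^{-4}$, 1000 iterations. Gradients are computed by
hand-derived reverse-mode differentiation through the whole
architecture and are verified against central finite differences in the
test suite.

**Initialization.** Projections ($W$, $M$) are Glorot-uniform;
attention vectors ($v_1$, $v_2$, $v_{self}$, $v_{nei}$) start at zero,
so the first forward pass uses the prior-only attention — a meaningful
warm start in which the genomic-distance kernel alone drives the
integration. One seed controls everything; two runs with the same seed
are bit-identical.

## From attention to called links

After training, the peak-side attention (the weight each peak's
normalized neighborhood assigns to each connected gene, self-loop
included) is pooled over all peak–gene pairs, excluding self-attention,
and mapped linearly onto $[0, 1]$. A two-component Gaussian mixture is
fitted to these scores by EM (k-means++ initialization, 500 iterations
maximum, log-likelihood tolerance $10^{-8}$), and the calling threshold
$\theta$ is the density intersection of the two components between
their means — the point of equal posterior membership — found by
bracketed root search at tolerance $10^{-6}$. Links with score
$\geq \theta$ are called. When the score distribution is not bimodal
(no crossing between the means), the fit refuses with an error rather
than fabricating a cutoff, and a manual threshold can be supplied to
`call_links()`. Pooling uses the peak→gene direction only; the
gene-side direction is available from the same attention object.

Called links can be compared against external benchmarks supplied as
plain tables: eQTL-style point loci (a pair is supported when a locus
associated with the gene falls inside the peak) or enhancer-style
intervals (supported on overlap), with evaluation restricted to
benchmark genes and summarized by a tie-corrected rank AUROC.

## Downstream analysis

The final spot embedding is the elementwise average $(f_i + g_i)/2$.
Clustering uses Louvain on the union-symmetrized kNN graph
(`k_neighbors = 15`) or a full-covariance Gaussian mixture (`mclust`)
when the number of domains is known. The Louvain default resolution is
0.1: the intended use is spatial-*domain* discovery, where a tissue
section carries a handful of coherent regions, and modularity
optimization at resolution 1 on graphs of a few hundred spots
systematically fragments such regions into subclusters; 0.1 is also the
resolution the analyses this package follows used when a low-resolution
Louvain was called for. Users resolving finer substructure should raise
it.

Markers per domain come from two-sided Wilcoxon rank-sum tests
(in-cluster vs rest) with Benjamini–Hochberg adjustment within each
cluster; effect sizes are differences of means on the preprocessed
(log) scale. Agreement with reference labels is measured by the
standard contingency-table metrics (Rand, adjusted Rand, adjusted and
normalized mutual information with arithmetic normalization,
homogeneity/completeness/V-measure, Fowlkes–Mallows), all implemented
from their definitions and cross-checked against brute-force pair
counting in the tests. Without reference labels, clustering quality is
scored by the intraclass correlation: per feature the one-way
random-effects ICC(1), $(MSB - MSW)/(MSB + (\bar k - 1) MSW)$ with
clusters as groups, averaged over features within a modality and across
the two modalities by an unweighted mean. The one-way form and the
unweighted combination are documented choices; features with no
variance contribute 0.

## Preprocessing

* RNA: per-spot scaling to a common library size ($10^4$), then
  $\log(1+x)$, then the 3000 most variable genes of the transformed
  matrix (ties broken by column index). Normalize-then-log is chosen
  over log-then-normalize because only the former makes the output
  invariant to per-spot sequencing depth.
* ATAC: the 50,000 most variable peaks, then TF-IDF with
  $TF_{ij} = x_{ij}/\sum_j x_{ij}$ and the log-smoothed
  $IDF_j = \ln(1 + N/(1 + df_j))$ — one of several TF-IDF dialects in
  use for accessibility data; this one is documented here and kept
  configurable — then library-size scaling and $\log(1+x)$ of the
  TF-IDF matrix.
* Protein (ADT): centered log-ratio per spot with pseudocount 1.

## The synthetic tissue generator

`simulate_tissue()` is the package's test bed and is itself first-class
code. It emulates the joint structure the model exploits: a
`20 x 20` grid of spots (rook adjacency) split into 4 horizontal stripe
domains; 150 genes assigned cyclically to domain programs, with Poisson
rates `5` (background) elevated by `exp(1.5)` in the marker domain; one
planted cis-peak per gene whose accessibility rate copies 80% of the
gene's (rescaled) program plus 20% background at ATAC rate `2`; and two
decoy peaks per gene placed in the same ±150 kb window around the TSS
with flat background rates. Genes sit 1 Mb apart, ten per synthetic
chromosome, so each peak's window contains exactly one gene and the
planted-link ground truth stays clean. Distances of planted and decoy
peaks are drawn from the same uniform window — deliberately, so that
the distance prior carries *no* information about which peaks are real
links and any ranking signal must come from the learned attention.

A thin protein variant (`modality2 = "protein"`) replaces the peaks
with one ADT per gene whose counts track the coded gene's program
through the same mixing weight, exercising the coding-map feature graph
end to end.

What the generator does not emulate: platform artifacts (spot swapping,
lateral diffusion), over-dispersion beyond Poisson (a negative-binomial
knob is the natural extension), batch structure, and the irregular
domain geometries of real tissue. Passing tests on this generator
therefore demonstrate the machinery end to end — preprocessing, graph
construction, optimization, link calling, clustering, evaluation — on
data whose generative structure matches the model's assumptions; they
do not by themselves establish performance on real assays.

## Numerical choices and degenerate inputs

* Attention normalizations are exact softmaxes over explicit edge
  lists; every neighborhood (cross and within) sums to 1 and this is
  asserted after forward passes in the tests.
* The sum-of-norms reconstruction gradient at a zero-residual spot is
  defined as 0 (the subgradient choice).
* Spots with all-zero counts cannot be depth-normalized and are
  reported by id as errors, as are zero-norm embeddings in the cosine
  similarity.
* HVG and top-peak selection are deterministic with ties broken by
  original column order.
* The EM variance floor is $10^{-12}$; a mixture collapse or a missing
  density crossing is an error, never a silent fallback.
* kNN spatial graphs are symmetrized by union so the adjacency is
  symmetric, as the within-modality equations assume.

## Problem sizes used in the checks

The bundled end-to-end checks run the default generator (400 spots, 150
genes, 450 peaks) with the default architecture (hidden widths 512 and
30) for the default 1000 iterations; unit tests use scaled-down
instances (tens of spots, hidden widths of a few units) chosen to keep
the whole suite fast while exercising identical code paths.

## Known limitations

* The cross-modality coefficient $e_{fg} = \sigma(v_1^\top X_{(f)} +
  v_2^\top X_{(g)})$ is *additive* in the two profiles: it contains no
  interaction term, so pair-specific evidence (e.g. the spatial
  correlation between a particular peak and a particular gene) can
  influence a score only through the per-feature projections and the
  competition inside each neighborhood's normalization. On synthetic
  data whose planted and decoy peaks are distance-matched and
  marginally identical, the learned ranking signal emerges very slowly
  under the default optimization budget; the structure-recovery check
  on link ranking documents exactly this behavior. Embedding quality
  does not suffer: domains are recovered essentially perfectly.
* Full-batch training holds all intermediates densely; the intended
  regime is $10^3$–$10^4$ spots and a few thousand features.
* Attention is single-headed, two modalities only, no histology
  integration; weighted-nearest-neighbor clustering of the two
  embeddings is not reimplemented — embeddings are exported for
  external tools instead.
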