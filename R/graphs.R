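#' Genomic distance between a peak interval and a gene TSS
#'
#' Returns 0 when the TSS falls inside the 0-based half-open interval
#' `[start, end)`, otherwise the distance from the TSS to the nearest
#' retained base, `max(start - tss, tss - (end - 1))`. Returns `NA` when
#' the two features sit on different chromosomes (no edge). Vectorized.
#'
#' @param peak_chrom,peak_start,peak_end peak interval (0-based half-open).
#' @param gene_chrom,gene_tss gene chromosome and 0-based TSS.
#' @return numeric distance in bp, or `NA` across chromosomes.
#' @export
genomic_distance <- function(peak_chrom, peak_start, peak_end,
                             gene_chrom, gene_tss) {
  if (anyNA(peak_start) || anyNA(peak_end) || anyNA(gene_tss) ||
      anyNA(peak_chrom) || anyNA(gene_chrom))
    stop("missing coordinates in genomic_distance()")
  d <- pmax(peak_start - gene_tss, gene_tss - (peak_end - 1))
  d <- pmax(d, 0)
  d[peak_chrom != gene_chrom] <- NA_real_
  d
}

#' Genomic-distance prior kernel
#'
#' `exp(((dist + bp_width) / bp_width)^(-0.75))`: equals `e` at distance 0
#' and decays strictly monotonically towards (but never reaching) 1 as the
#' distance grows.
#'
#' @param dist nonnegative distance in bp (vectorized).
#' @param bp_width kernel bandwidth in bp (default 400).
#' @return prior weight in `(1, e]`.
#' @export
distance_prior <- function(dist, bp_width = 400) {
  if (bp_width <= 0) stop("bp_width must be positive")
  if (any(dist < 0)) stop("negative genomic distance")
  exp(((dist + bp_width) / bp_width)^(-0.75))
}

#' Cross-modality feature connectivity graph
#'
#' Builds the feature graph joining the two modalities.
#'
#' * `mode = "genomic"` (peak-gene): an edge for every peak-gene pair on
#'   the same chromosome within `max_dist` bp of the TSS, weighted by
#'   [distance_prior()]; self-loop priors use distance 0 (value `e`).
#' * `mode = "coding"` (protein-gene): an edge iff the gene is listed in
#'   the protein's `coding_gene_ids`, prior 1; self-loop prior 1.
#' * `mode = "uniform"`: edges from `association_ids`, prior 1.
#'
#' @param annotations a [feature_annotation()] table restricted to the
#'   features of both modalities (order defines node order).
#' @param mode `"genomic"`, `"coding"` or `"uniform"`.
#' @param bp_width prior kernel bandwidth in bp.
#' @param max_dist maximum peak-TSS distance in bp for an edge.
#' @return an object of class `feature_graph` with fields `nodes`, `kind`,
#'   `edges` (data.frame `feature1`, `feature2`, `dist`, `prior`;
#'   `feature1` is the peak/protein side), `self_prior`, and precomputed
#'   directed index arrays (`ti`, `si`, `prior`) covering both
#'   orientations of every edge plus the self-loops.
#' @export
build_feature_graph <- function(annotations, mode = c("genomic", "coding", "uniform"),
                                bp_width = 400, max_dist = 150000) {
  mode <- match.arg(mode)
  ann <- as.data.frame(annotations)
  nodes <- ann$feature_id
  kind <- ann$kind
  m <- length(nodes)
  if (mode == "genomic") {
    pk <- which(kind == "peak")
    gn <- which(kind == "gene")
    if (!length(pk) || !length(gn)) stop("genomic mode needs peaks and genes")
    # same-chromosome candidate pairs only
    ed <- NULL
    for (ch in intersect(unique(ann$chrom[pk]), unique(ann$chrom[gn]))) {
      p <- pk[ann$chrom[pk] == ch]
      g <- gn[ann$chrom[gn] == ch]
      grid <- expand.grid(p = p, g = g)
      d <- genomic_distance(ann$chrom[grid$p], ann$start[grid$p], ann$end[grid$p],
                            ann$chrom[grid$g], ann$tss[grid$g])
      ok <- !is.na(d) & d <= max_dist
      if (any(ok))
        ed <- rbind(ed, data.frame(i = grid$p[ok], j = grid$g[ok], dist = d[ok]))
    }
    if (is.null(ed)) ed <- data.frame(i = integer(0), j = integer(0), dist = numeric(0))
    prior <- distance_prior(ed$dist, bp_width)
    self_prior <- rep(distance_prior(0, bp_width), m)
  } else if (mode == "coding") {
    pr <- which(kind == "protein")
    gn <- which(kind == "gene")
    ii <- integer(0); jj <- integer(0)
    for (f in pr) {
      ids <- strsplit(ann$coding_gene_ids[f], ",", fixed = TRUE)[[1]]
      ids <- trimws(ids[!is.na(ids) & nzchar(ids)])
      hit <- match(ids, nodes[gn])
      if (anyNA(hit)) {
        warning("gene(s) ", paste(ids[is.na(hit)], collapse = ", "),
                " referenced by protein ", nodes[f],
                " absent from the gene list; edge dropped")
        hit <- hit[!is.na(hit)]
      }
      ii <- c(ii, rep(f, length(hit))); jj <- c(jj, gn[hit])
    }
    ed <- data.frame(i = ii, j = jj, dist = NA_real_)
    prior <- rep(1, nrow(ed))
    self_prior <- rep(1, m)
  } else {
    mt <- which(kind %in% c("metabolite", "protein"))
    ii <- integer(0); jj <- integer(0)
    for (f in mt) {
      ids <- strsplit(ann$association_ids[f], ",", fixed = TRUE)[[1]]
      ids <- trimws(ids[!is.na(ids) & nzchar(ids)])
      hit <- match(ids, nodes)
      if (anyNA(hit)) {
        warning("association partner(s) absent for ", nodes[f], "; edge dropped")
        hit <- hit[!is.na(hit)]
      }
      ii <- c(ii, rep(f, length(hit))); jj <- c(jj, hit)
    }
    ed <- data.frame(i = ii, j = jj, dist = NA_real_)
    prior <- rep(1, nrow(ed))
    self_prior <- rep(1, m)
  }
  edges <- data.frame(feature1 = nodes[ed$i], feature2 = nodes[ed$j],
                      dist = ed$dist, prior = prior,
                      stringsAsFactors = FALSE)
  # directed expansion (both orientations) plus self-loops, for attention
  ti <- c(ed$i, ed$j, seq_len(m))
  si <- c(ed$j, ed$i, seq_len(m))
  pv <- c(prior, prior, self_prior)
  structure(list(nodes = nodes, kind = kind, edges = edges,
                 self_prior = self_prior, mode = mode,
                 bp_width = bp_width, max_dist = max_dist,
                 ti = ti, si = si, prior = pv),
            class = "feature_graph")
}

#' @export
print.feature_graph <- function(x, ...) {
  cat(sprintf("<feature_graph> mode=%s: %d nodes, %d cross-modality edges\n",
              x$mode, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Spot spatial neighborhood graph
#'
#' Neighborhoods follow the array layout: `grid4` (rook adjacency),
#' `grid8` (3x3 block), `hex6` (hexagonal lattice in Visium array
#' indexing: offsets `(0, +-2)` and `(+-1, +-1)`), or `knn` (Euclidean
#' k-nearest neighbors on `(x, y)`, symmetrized by union). Every spot is
#' its own neighbor (self-loops).
#'
#' @param coords a [spot_coordinates()] table.
#' @param layout one of `"grid4"`, `"grid8"`, `"hex6"`, `"knn"`.
#' @param k neighbor count for `knn`.
#' @return an object of class `spatial_graph` with the symmetric adjacency
#'   `S` (sparse, unit diagonal) and directed edge arrays `ii`, `jj`
#'   (including self-loops).
#' @export
build_spatial_graph <- function(coords, layout = c("grid4", "grid8", "hex6", "knn"),
                                k = NULL) {
  layout <- match.arg(layout)
  n <- nrow(coords)
  if (layout %in% c("grid4", "grid8", "hex6")) {
    r <- coords$array_row; c0 <- coords$array_col
    if (anyNA(r) || anyNA(c0))
      stop("layout '", layout, "' requires array_row/array_col")
    key <- paste(r, c0)
    if (anyDuplicated(key)) stop("duplicate grid index: ", key[duplicated(key)][1])
    offs <- switch(layout,
                   grid4 = cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1)),
                   grid8 = cbind(rep(-1:1, each = 3), rep(-1:1, 3))[-5, ],
                   hex6 = cbind(c(0, 0, -1, -1, 1, 1), c(-2, 2, -1, 1, -1, 1)))
    idx <- seq_len(n)
    ii <- integer(0); jj <- integer(0)
    lookup <- stats::setNames(idx, key)
    for (o in seq_len(nrow(offs))) {
      nk <- paste(r + offs[o, 1], c0 + offs[o, 2])
      hit <- lookup[nk]
      ok <- !is.na(hit)
      ii <- c(ii, idx[ok]); jj <- c(jj, unname(hit[ok]))
    }
  } else {
    if (is.null(k)) stop("knn layout requires k")
    if (k >= n) stop("k_neighbors must be smaller than the number of spots")
    d <- as.matrix(stats::dist(cbind(coords$x, coords$y)))
    diag(d) <- Inf
    nb <- apply(d, 1, function(row) order(row)[seq_len(k)])
    ii <- rep(seq_len(n), each = k); jj <- as.vector(nb)
    # symmetrize by union
    und <- unique(rbind(cbind(ii, jj), cbind(jj, ii)))
    ii <- und[, 1]; jj <- und[, 2]
  }
  ii <- c(ii, seq_len(n)); jj <- c(jj, seq_len(n))
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  S@x[] <- 1  # guard duplicate edges
  if (!Matrix::isSymmetric(S)) stop("internal error: spatial graph not symmetric")
  structure(list(spot_ids = coords$spot_id, S = S, ii = ii, jj = jj,
                 layout = layout),
            class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("<spatial_graph> layout=%s: %d spots, mean neighborhood size %.2f\n",
              x$layout, length(x$spot_ids), length(x$ii) / length(x$spot_ids)))
  invisible(x)
}

#' Neighbor sets of a spatial graph
#' @param graph a `spatial_graph`.
#' @return list of integer neighbor indices per spot (self included).
#' @export
neighbor_sets <- function(graph) {
  split(graph$jj, factor(graph$ii, levels = seq_along(graph$spot_ids)))
}
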