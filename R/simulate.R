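#' Synthetic tissue simulation configuration
#'
#' The generator emulates a layered tissue profiled with a paired
#' RNA + ATAC assay: spots on a rectangular grid partitioned into
#' horizontal-stripe domains, domain-specific gene expression programs,
#' one cis-linked peak per gene whose accessibility tracks the gene's
#' program, and decoy peaks in the same genomic windows with independent
#' noise.
#'
#' @param grid `(rows, cols)` of the spot lattice.
#' @param n_domains number of horizontal stripe domains.
#' @param n_genes number of genes.
#' @param linked_peaks_per_gene,decoy_peaks_per_gene planted and decoy
#'   peaks per gene.
#' @param max_link_dist maximum TSS distance of any planted or decoy peak
#'   (bp).
#' @param domain_effect log-fold elevation of a domain's marker program.
#' @param base_rate_rna,base_rate_atac Poisson means of background counts.
#' @param link_strength fraction of a linked peak's rate copied from its
#'   gene's (rescaled) program; the remainder is background.
#' @param modality2 `"atac"` (peaks with a genomic-distance feature
#'   graph) or `"protein"` (a thin coding-map variant: one ADT per gene,
#'   counts tracking the coded gene's program with the same
#'   `link_strength` mixing, no genomic coordinates).
#' @param seed RNG seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(grid = c(20, 20), n_domains = 4, n_genes = 150,
                       linked_peaks_per_gene = 1, decoy_peaks_per_gene = 2,
                       max_link_dist = 150000, domain_effect = 1.5,
                       base_rate_rna = 5, base_rate_atac = 2,
                       link_strength = 0.8, modality2 = c("atac", "protein"),
                       seed = 0) {
  modality2 <- match.arg(modality2)
  stopifnot(all(grid >= 1), n_domains >= 1, n_genes >= 1,
            linked_peaks_per_gene >= 1, decoy_peaks_per_gene >= 0,
            max_link_dist > 0, base_rate_rna > 0, base_rate_atac > 0,
            link_strength >= 0, link_strength <= 1)
  structure(list(grid = grid, n_domains = n_domains, n_genes = n_genes,
                 linked_peaks_per_gene = linked_peaks_per_gene,
                 decoy_peaks_per_gene = decoy_peaks_per_gene,
                 max_link_dist = max_link_dist, domain_effect = domain_effect,
                 base_rate_rna = base_rate_rna, base_rate_atac = base_rate_atac,
                 link_strength = link_strength, modality2 = modality2,
                 seed = seed),
            class = "sim_config")
}

#' Simulate a layered spatial multi-omics tissue
#'
#' Spots sit on a `rows x cols` grid (grid4 layout) split into
#' `n_domains` horizontal stripes. Genes are assigned cyclically to
#' domain programs: gene g marking domain d has Poisson rate
#' `base_rate_rna * exp(domain_effect)` in spots of d and `base_rate_rna`
#' elsewhere. Each gene receives a TSS on a synthetic chromosome (10
#' genes per chromosome, 1 Mb spacing, so decoy contamination across
#' genes is negligible); its linked peak(s) are placed uniformly within
#' `max_link_dist` of the TSS with ATAC rate
#' `link_strength * program(rescaled to base_rate_atac) +
#' (1 - link_strength) * base_rate_atac`, while decoy peaks in the same
#' windows draw counts at the flat background rate.
#'
#' @param cfg a [sim_config()].
#' @return list with `dataset` (a raw [spatial_multiome()]) and `truth`
#'   (list: `domains` integer per spot, `links` data.frame of planted
#'   `(peak_id, gene_id)`, `programs` domain per gene).
#' @export
simulate_tissue <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  nr <- cfg$grid[1]; nc <- cfg$grid[2]
  n <- nr * nc
  if (nr < cfg$n_domains)
    stop("grid has fewer rows (", nr, ") than domains (", cfg$n_domains, ")")
  rows <- rep(seq_len(nr), each = nc)
  cols <- rep(seq_len(nc), times = nr)
  # contiguous horizontal stripes of (nearly) equal height
  domain <- as.integer(cut(rows, breaks = cfg$n_domains, labels = FALSE))
  spot_ids <- sprintf("spot_%03d_%03d", rows, cols)
  coords <- spot_coordinates(spot_ids, x = cols, y = rows,
                             array_row = rows, array_col = cols,
                             layout = "grid4")

  g_ids <- sprintf("gene_%03d", seq_len(cfg$n_genes))
  program <- ((seq_len(cfg$n_genes) - 1L) %% cfg$n_domains) + 1L
  # RNA rates: N x n_genes
  hi <- cfg$base_rate_rna * exp(cfg$domain_effect)
  rate_rna <- matrix(cfg$base_rate_rna, n, cfg$n_genes)
  for (gi in seq_len(cfg$n_genes))
    rate_rna[domain == program[gi], gi] <- hi
  X_rna <- matrix(stats::rpois(n * cfg$n_genes, rate_rna), n, cfg$n_genes)

  if (cfg$modality2 == "protein") {
    # thin coding-map variant: one ADT per gene tracking its program
    pr_ids <- sprintf("adt_%03d", seq_len(cfg$n_genes))
    rate_adt <- cfg$link_strength *
      sweep(rate_rna, 2, colMeans(rate_rna), `/`) * cfg$base_rate_atac +
      (1 - cfg$link_strength) * cfg$base_rate_atac
    X_adt <- matrix(stats::rpois(n * cfg$n_genes, rate_adt), n, cfg$n_genes)
    chrom_of <- paste0("chrS", (seq_len(cfg$n_genes) - 1L) %/% 10L + 1L)
    tss <- ((seq_len(cfg$n_genes) - 1L) %% 10L) * 1e6 + 5e5
    ann <- bind_annotations(
      feature_annotation(g_ids, "gene", chrom = chrom_of, tss = tss,
                         strand = "+"),
      feature_annotation(pr_ids, "protein", coding_gene_ids = g_ids))
    dataset <- spatial_multiome(
      modality_matrix(X_rna, spot_ids, g_ids, "rna", "raw"),
      modality_matrix(X_adt, spot_ids, pr_ids, "protein", "raw"),
      ann, coords)
    truth <- list(domains = stats::setNames(domain, spot_ids),
                  links = data.frame(peak_id = pr_ids, gene_id = g_ids,
                                     stringsAsFactors = FALSE),
                  decoys = data.frame(peak_id = character(0),
                                      gene_id = character(0)),
                  programs = stats::setNames(program, g_ids))
    return(list(dataset = dataset, truth = truth))
  }

  # genomic layout: 10 genes per synthetic chromosome, 1 Mb apart
  chrom_of <- paste0("chrS", (seq_len(cfg$n_genes) - 1L) %/% 10L + 1L)
  tss <- ((seq_len(cfg$n_genes) - 1L) %% 10L) * 1e6 + 5e5

  peak_w <- 500
  pk_per_gene <- cfg$linked_peaks_per_gene + cfg$decoy_peaks_per_gene
  n_peaks <- cfg$n_genes * pk_per_gene
  pk_gene <- rep(seq_len(cfg$n_genes), each = pk_per_gene)
  pk_linked <- rep(c(rep(TRUE, cfg$linked_peaks_per_gene),
                     rep(FALSE, cfg$decoy_peaks_per_gene)), cfg$n_genes)
  # uniform offsets keeping the whole peak within max_link_dist of the TSS
  off <- round(stats::runif(n_peaks, -(cfg$max_link_dist - peak_w),
                            cfg$max_link_dist - peak_w))
  pk_start <- tss[pk_gene] + off - peak_w %/% 2
  pk_end <- pk_start + peak_w
  pk_chrom <- chrom_of[pk_gene]
  pk_ids <- sprintf("peak_%04d", seq_len(n_peaks))

  # ATAC rates: linked peaks track the gene program (rescaled to the ATAC
  # count scale); decoys are flat background
  rate_atac <- matrix(cfg$base_rate_atac, n, n_peaks)
  for (pi in which(pk_linked)) {
    prog <- rate_rna[, pk_gene[pi]]
    scaled <- prog / mean(prog) * cfg$base_rate_atac
    rate_atac[, pi] <- cfg$link_strength * scaled +
      (1 - cfg$link_strength) * cfg$base_rate_atac
  }
  X_atac <- matrix(stats::rpois(n * n_peaks, rate_atac), n, n_peaks)

  ann <- bind_annotations(
    feature_annotation(g_ids, "gene", chrom = chrom_of, tss = tss,
                       strand = rep(c("+", "-"), length.out = cfg$n_genes)),
    feature_annotation(pk_ids, "peak", chrom = pk_chrom, start = pk_start,
                       end = pk_end))
  dataset <- spatial_multiome(
    modality_matrix(X_rna, spot_ids, g_ids, "rna", "raw"),
    modality_matrix(X_atac, spot_ids, pk_ids, "atac", "raw"),
    ann, coords)
  truth <- list(domains = stats::setNames(domain, spot_ids),
                links = data.frame(peak_id = pk_ids[pk_linked],
                                   gene_id = g_ids[pk_gene[pk_linked]],
                                   stringsAsFactors = FALSE),
                decoys = data.frame(peak_id = pk_ids[!pk_linked],
                                    gene_id = g_ids[pk_gene[!pk_linked]],
                                    stringsAsFactors = FALSE),
                programs = stats::setNames(program, g_ids))
  list(dataset = dataset, truth = truth)
}

#' Write a dataset in the on-disk formats [read_dataset()] consumes
#'
#' MatrixMarket + features/barcodes per modality, peak BED, gene TSV,
#' coordinate CSV.
#'
#' @param dataset a [spatial_multiome()].
#' @param dir output directory (created).
#' @return named list of paths suitable for [read_dataset()].
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wmod <- function(m, tag) {
    mp <- file.path(dir, paste0(tag, "_matrix.mtx"))
    fp <- file.path(dir, paste0(tag, "_features.tsv"))
    bp <- file.path(dir, paste0(tag, "_barcodes.tsv"))
    Matrix::writeMM(methods::as(methods::as(Matrix::t(
      Matrix::Matrix(m$values, sparse = TRUE)), "CsparseMatrix"), "generalMatrix"), mp)
    writeLines(m$feature_ids, fp)
    writeLines(m$spot_ids, bp)
    c(matrix = mp, features = fp, barcodes = bp)
  }
  p1 <- wmod(dataset$modality1, "mod1")
  p2 <- wmod(dataset$modality2, "mod2")
  ann <- dataset$annotations
  gn <- ann[ann$kind == "gene", ]
  pk <- ann[ann$kind == "peak", ]
  genes_path <- file.path(dir, "genes.tsv")
  utils::write.table(data.frame(gene_id = gn$feature_id, chrom = gn$chrom,
                                tss = gn$tss, strand = gn$strand),
                     genes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  peaks_path <- file.path(dir, "peaks.bed")
  if (nrow(pk))
    writeLines(sprintf("%s\t%d\t%d\t%s", pk$chrom, as.integer(pk$start),
                       as.integer(pk$end), pk$feature_id), peaks_path)
  pr <- ann[ann$kind == "protein", ]
  proteins_path <- file.path(dir, "proteins.tsv")
  if (nrow(pr))
    utils::write.table(data.frame(protein_id = pr$feature_id,
                                  coding_gene_ids = pr$coding_gene_ids),
                       proteins_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  coords_path <- file.path(dir, "coords.csv")
  utils::write.csv(as.data.frame(dataset$coords), coords_path, row.names = FALSE)
  list(mod1_matrix = unname(p1["matrix"]), mod1_features = unname(p1["features"]),
       mod1_barcodes = unname(p1["barcodes"]),
       mod2_matrix = unname(p2["matrix"]), mod2_features = unname(p2["features"]),
       mod2_barcodes = unname(p2["barcodes"]),
       genes = genes_path, peaks = if (nrow(pk)) peaks_path else NULL,
       proteins = if (nrow(pr)) proteins_path else NULL,
       coords = coords_path)
}
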