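#' Spot-by-feature matrix for one modality
#'
#' Thin container pairing a numeric matrix (dense or sparse) with ordered
#' spot and feature identifiers, the modality it measures, and whether the
#' values are raw counts or preprocessed.
#'
#' @param values numeric matrix or `Matrix::dgCMatrix`, spots in rows,
#'   features in columns.
#' @param spot_ids character vector of unique spot barcodes, one per row.
#' @param feature_ids character vector of unique feature identifiers, one
#'   per column.
#' @param modality one of `"rna"`, `"atac"`, `"protein"`, `"metabolite"`.
#' @param layer `"raw"` for counts, `"preprocessed"` after normalization.
#' @return an object of class `modality_matrix`.
#' @export
modality_matrix <- function(values, spot_ids, feature_ids,
                            modality = c("rna", "atac", "protein", "metabolite"),
                            layer = c("raw", "preprocessed")) {
  modality <- match.arg(modality)
  layer <- match.arg(layer)
  spot_ids <- as.character(spot_ids)
  feature_ids <- as.character(feature_ids)
  if (nrow(values) != length(spot_ids))
    stop("row count (", nrow(values), ") does not match number of spot_ids (",
         length(spot_ids), ")")
  if (ncol(values) != length(feature_ids))
    stop("column count (", ncol(values), ") does not match number of feature_ids (",
         length(feature_ids), ")")
  if (anyDuplicated(spot_ids)) stop("spot_ids must be unique")
  if (anyDuplicated(feature_ids)) stop("feature_ids must be unique")
  rownames(values) <- spot_ids
  colnames(values) <- feature_ids
  structure(list(values = values, spot_ids = spot_ids,
                 feature_ids = feature_ids, modality = modality,
                 layer = layer),
            class = "modality_matrix")
}

#' @export
print.modality_matrix <- function(x, ...) {
  cat(sprintf("<modality_matrix> %s [%s]: %d spots x %d features\n",
              x$modality, x$layer, length(x$spot_ids), length(x$feature_ids)))
  invisible(x)
}

#' @export
dim.modality_matrix <- function(x) dim(x$values)

#' Per-feature genomic annotation table
#'
#' Builds the feature annotation table covering genes, peaks, proteins and
#' metabolites. Peaks carry a 0-based half-open interval `[start, end)`;
#' genes carry a single 0-based TSS position; proteins carry the ids of the
#' genes coding them (comma-separated).
#'
#' @param feature_id character vector.
#' @param kind one of `"gene"`, `"peak"`, `"protein"`, `"metabolite"` per
#'   feature.
#' @param chrom,start,end,tss,strand optional genomic coordinates
#'   (`NA` where not applicable).
#' @param coding_gene_ids optional comma-separated gene ids per protein.
#' @param association_ids optional comma-separated partner ids (metabolites).
#' @return a `data.frame` with class `feature_annotation`.
#' @export
feature_annotation <- function(feature_id, kind, chrom = NA, start = NA,
                               end = NA, tss = NA, strand = NA,
                               coding_gene_ids = NA, association_ids = NA) {
  n <- length(feature_id)
  ann <- data.frame(feature_id = as.character(feature_id),
                    kind = as.character(kind),
                    chrom = rep_len(as.character(chrom), n),
                    start = rep_len(as.numeric(start), n),
                    end = rep_len(as.numeric(end), n),
                    tss = rep_len(as.numeric(tss), n),
                    strand = rep_len(as.character(strand), n),
                    coding_gene_ids = rep_len(as.character(coding_gene_ids), n),
                    association_ids = rep_len(as.character(association_ids), n),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ann$feature_id)) stop("feature ids must be unique")
  bad_kind <- setdiff(unique(ann$kind), c("gene", "peak", "protein", "metabolite"))
  if (length(bad_kind)) stop("unknown feature kind: ", paste(bad_kind, collapse = ", "))
  pk <- ann$kind == "peak"
  if (any(pk & (is.na(ann$chrom) | is.na(ann$start) | is.na(ann$end))))
    stop("peaks require chrom, start and end")
  if (any(pk & !(ann$start < ann$end)))
    stop("peak intervals must satisfy start < end (0-based half-open)")
  gn <- ann$kind == "gene"
  if (any(gn & (is.na(ann$chrom) | is.na(ann$tss))))
    stop("genes require chrom and tss")
  class(ann) <- c("feature_annotation", "data.frame")
  ann
}

#' Spatial coordinates of the spots
#'
#' @param spot_id character vector.
#' @param x,y continuous positions.
#' @param array_row,array_col optional integer grid indices (required for
#'   grid/hex layouts).
#' @param layout layout hint: `"grid4"`, `"grid8"`, `"hex6"` or `"generic"`.
#' @return a `data.frame` with class `spot_coordinates` and a `layout`
#'   attribute.
#' @export
spot_coordinates <- function(spot_id, x, y, array_row = NA, array_col = NA,
                             layout = c("generic", "grid4", "grid8", "hex6")) {
  layout <- match.arg(layout)
  n <- length(spot_id)
  co <- data.frame(spot_id = as.character(spot_id), x = as.numeric(x),
                   y = as.numeric(y),
                   array_row = rep_len(suppressWarnings(as.integer(array_row)), n),
                   array_col = rep_len(suppressWarnings(as.integer(array_col)), n),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(co$spot_id)) stop("spot ids must be unique")
  if (layout %in% c("grid4", "grid8", "hex6") &&
      (anyNA(co$array_row) || anyNA(co$array_col)))
    stop("layout '", layout, "' requires array_row and array_col")
  attr(co, "layout") <- layout
  class(co) <- c("spot_coordinates", "data.frame")
  co
}

#' Paired spatial multi-omics dataset
#'
#' Bundles the two modality matrices with the feature annotation covering
#' the union of their features and the spot coordinates. Both matrices must
#' share the same spots; modality 1's barcode order is canonical and
#' modality 2 is reindexed to match.
#'
#' @param modality1,modality2 [modality_matrix()] objects over the same
#'   spots.
#' @param annotations a [feature_annotation()] table covering every feature
#'   of both matrices.
#' @param coords a [spot_coordinates()] table covering every spot.
#' @return an object of class `spatial_multiome`.
#' @export
spatial_multiome <- function(modality1, modality2, annotations, coords) {
  stopifnot(inherits(modality1, "modality_matrix"),
            inherits(modality2, "modality_matrix"),
            inherits(annotations, "feature_annotation"),
            inherits(coords, "spot_coordinates"))
  d1 <- setdiff(modality1$spot_ids, modality2$spot_ids)
  d2 <- setdiff(modality2$spot_ids, modality1$spot_ids)
  if (length(d1) || length(d2))
    stop("mismatched barcodes between modalities; only in modality1: {",
         paste(utils::head(d1, 10), collapse = ", "),
         "}; only in modality2: {",
         paste(utils::head(d2, 10), collapse = ", "), "}")
  if (!identical(modality1$spot_ids, modality2$spot_ids)) {
    ord <- match(modality1$spot_ids, modality2$spot_ids)
    modality2 <- modality_matrix(modality2$values[ord, , drop = FALSE],
                                 modality2$spot_ids[ord],
                                 modality2$feature_ids,
                                 modality2$modality, modality2$layer)
  }
  feats <- c(modality1$feature_ids, modality2$feature_ids)
  missing_ann <- setdiff(feats, annotations$feature_id)
  if (length(missing_ann))
    stop("features absent from annotation: ",
         paste(utils::head(missing_ann, 10), collapse = ", "))
  missing_co <- setdiff(modality1$spot_ids, coords$spot_id)
  if (length(missing_co))
    stop("spots absent from coordinates: ",
         paste(utils::head(missing_co, 10), collapse = ", "))
  lay <- attr(coords, "layout")
  coords <- coords[match(modality1$spot_ids, coords$spot_id), , drop = FALSE]
  rownames(coords) <- NULL
  attr(coords, "layout") <- lay
  structure(list(modality1 = modality1, modality2 = modality2,
                 annotations = annotations, coords = coords),
            class = "spatial_multiome")
}

#' @export
print.spatial_multiome <- function(x, ...) {
  cat(sprintf("<spatial_multiome> %d spots; %s (%d features, %s) + %s (%d features, %s)\n",
              length(x$modality1$spot_ids),
              x$modality1$modality, length(x$modality1$feature_ids), x$modality1$layer,
              x$modality2$modality, length(x$modality2$feature_ids), x$modality2$layer))
  invisible(x)
}

read_mtx_modality <- function(matrix_path, features_path, barcodes_path,
                              modality, layer = "raw") {
  for (p in c(matrix_path, features_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- Matrix::readMM(matrix_path)       # features x spots (10x convention)
  if (any(dim(m) == 0L)) stop("empty matrix in ", matrix_path)
  feats <- readLines(features_path)
  bcs <- readLines(barcodes_path)
  feats <- feats[nzchar(feats)]
  bcs <- bcs[nzchar(bcs)]
  # feature files may be TSV with extra columns; first column is the id
  feats <- vapply(strsplit(feats, "\t", fixed = TRUE), `[[`, character(1), 1L)
  bcs <- vapply(strsplit(bcs, "\t", fixed = TRUE), `[[`, character(1), 1L)
  if (nrow(m) != length(feats))
    stop("matrix has ", nrow(m), " rows but ", length(feats), " features listed")
  if (ncol(m) != length(bcs))
    stop("matrix has ", ncol(m), " columns but ", length(bcs), " barcodes listed")
  modality_matrix(Matrix::t(m), bcs, feats, modality = modality, layer = layer)
}

#' Read peak intervals from a BED file
#'
#' BED coordinates are 0-based half-open. A fourth column, when present,
#' supplies the peak id; otherwise `chrom:start-end` is used.
#'
#' @param path BED3+ file.
#' @return a [feature_annotation()] table of peaks.
#' @export
read_peaks_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty BED file: ", path)
  parts <- strsplit(lines, "[ \t]+")  # canonical BED is tab-separated;
  nf <- lengths(parts)                # whitespace tolerated
  bad <- which(nf < 3L)
  if (length(bad))
    stop("malformed BED line ", bad[1], ": fewer than 3 fields")
  chrom <- vapply(parts, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | !(start < end))
  if (length(bad))
    stop("malformed BED line ", bad[1],
         ": start/end not numeric or start >= end")
  id <- ifelse(nf >= 4L, vapply(parts, function(p) p[min(4L, length(p))],
                                character(1)),
               paste0(chrom, ":", start, "-", end))
  feature_annotation(id, "peak", chrom = chrom, start = start, end = end)
}

#' Read gene annotation from a TSV file
#'
#' Expects a header with columns `gene_id`, `chrom`, `tss`, `strand`; the
#' TSS is a single 0-based position (already strand-resolved).
#'
#' @param path TSV file.
#' @return a [feature_annotation()] table of genes.
#' @export
read_genes_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stop("gene annotation lacks columns: ",
                         paste(miss, collapse = ", "))
  feature_annotation(tb$gene_id, "gene", chrom = tb$chrom, tss = tb$tss,
                     strand = tb$strand)
}

#' Combine feature annotation tables
#'
#' Row-binds per-kind [feature_annotation()] tables (genes, peaks,
#' proteins) into one table covering both modalities.
#'
#' @param ... `feature_annotation` tables.
#' @return a single `feature_annotation` table.
#' @export
bind_annotations <- function(...) {
  tabs <- list(...)
  ann <- do.call(rbind, lapply(tabs, function(t) as.data.frame(t)))
  rownames(ann) <- NULL
  class(ann) <- c("feature_annotation", "data.frame")
  if (anyDuplicated(ann$feature_id)) stop("feature ids must be unique")
  ann
}

#' Assemble a spatial multi-omics dataset from standard on-disk formats
#'
#' @param paths named list of file paths:
#'   * `mod1_matrix`, `mod1_features`, `mod1_barcodes`: MatrixMarket +
#'     feature/barcode text files for modality 1 (features x spots);
#'   * `mod2_matrix`, `mod2_features`, `mod2_barcodes`: same for modality 2;
#'   * `genes`: gene annotation TSV (`gene_id`, `chrom`, `tss`, `strand`);
#'   * `peaks`: BED file of peak intervals (required when modality 2 is
#'     `"atac"`);
#'   * `proteins` (optional): TSV with `protein_id`, `coding_gene_ids`;
#'   * `coords`: CSV with `spot_id`, `x`, `y` and optionally `array_row`,
#'     `array_col`.
#' @param layout spatial layout hint passed to [spot_coordinates()].
#' @param modalities character vector of length two naming the modalities,
#'   default `c("rna", "atac")`.
#' @return a [spatial_multiome()] dataset (raw layer).
#' @export
read_dataset <- function(paths, layout = "generic",
                         modalities = c("rna", "atac")) {
  m1 <- read_mtx_modality(paths$mod1_matrix, paths$mod1_features,
                          paths$mod1_barcodes, modalities[1])
  m2 <- read_mtx_modality(paths$mod2_matrix, paths$mod2_features,
                          paths$mod2_barcodes, modalities[2])
  ann_list <- list()
  if (!is.null(paths$genes)) ann_list <- c(ann_list, list(read_genes_tsv(paths$genes)))
  if (!is.null(paths$peaks)) ann_list <- c(ann_list, list(read_peaks_bed(paths$peaks)))
  if (!is.null(paths$proteins)) {
    tb <- utils::read.delim(paths$proteins, stringsAsFactors = FALSE)
    ann_list <- c(ann_list, list(
      feature_annotation(tb$protein_id, "protein",
                         coding_gene_ids = tb$coding_gene_ids)))
  }
  if (!length(ann_list)) stop("no feature annotation supplied")
  ann <- do.call(bind_annotations, ann_list)
  co <- utils::read.csv(paths$coords, stringsAsFactors = FALSE)
  co <- spot_coordinates(co$spot_id, co$x, co$y,
                         array_row = if ("array_row" %in% names(co)) co$array_row else NA,
                         array_col = if ("array_col" %in% names(co)) co$array_col else NA,
                         layout = layout)
  spatial_multiome(m1, m2, ann, co)
}

fmt_num <- function(x) {
  # 17 significant digits: lossless round trip for doubles
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

write_tsv17 <- function(df, path) {
  out <- df
  for (j in seq_along(out)) if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write analysis results to a directory
#'
#' Writes `embeddings.tsv` (spot_id + one column per latent dimension),
#' `links.tsv`, `clusters.tsv` and `metrics.json`. Floats are serialized
#' with 17 significant digits so re-reading reproduces them exactly.
#'
#' @param embeddings numeric matrix of per-spot embeddings with spot ids as
#'   row names, or `NULL` to skip.
#' @param links regulatory link `data.frame` (see [call_links()]), or
#'   `NULL` to write nothing.
#' @param clusters integer vector of per-spot labels named by spot id, or
#'   `NULL`.
#' @param out_dir output directory, created if missing.
#' @param metrics optional named list written to `metrics.json`.
#' @return invisibly, a character vector of files written (the manifest).
#' @export
write_results <- function(embeddings = NULL, links = NULL, clusters = NULL,
                          out_dir, metrics = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) stop("cannot write to directory: ", out_dir)
  written <- character(0)
  if (!is.null(embeddings)) {
    df <- data.frame(spot_id = rownames(embeddings),
                     as.data.frame(unname(embeddings)),
                     stringsAsFactors = FALSE)
    names(df) <- c("spot_id", paste0("dim", seq_len(ncol(embeddings))))
    p <- file.path(out_dir, "embeddings.tsv")
    write_tsv17(df, p); written <- c(written, p)
  }
  if (!is.null(links)) {
    p <- file.path(out_dir, "links.tsv")
    write_tsv17(as.data.frame(links), p); written <- c(written, p)
  }
  if (!is.null(clusters)) {
    df <- data.frame(spot_id = names(clusters),
                     cluster = as.integer(clusters),
                     stringsAsFactors = FALSE)
    p <- file.path(out_dir, "clusters.tsv")
    write_tsv17(df, p); written <- c(written, p)
  }
  if (!is.null(metrics)) {
    p <- file.path(out_dir, "metrics.json")
    jsonlite::write_json(metrics, p, auto_unbox = TRUE, digits = NA)
    written <- c(written, p)
  }
  invisible(written)
}

#' Read embeddings written by [write_results()]
#' @param path `embeddings.tsv` file.
#' @return numeric matrix with spot ids as row names.
#' @export
read_embeddings <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$spot_id
  m
}
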