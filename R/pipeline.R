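#' Default run configuration
#'
#' A single declarative configuration (YAML-serializable) driving every
#' pipeline stage; flags on the command line override file values. Every
#' stage writes the resolved configuration next to its outputs.
#'
#' @param seed global seed.
#' @param sim [sim_config()] fields for the `simulate` stage.
#' @param preprocess [preprocess_config()] fields.
#' @param graph feature/spatial graph options.
#' @param train [train_config()] fields.
#' @param cluster clustering options.
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 0,
                               sim = list(),
                               preprocess = list(),
                               graph = list(mode = "genomic", bp_width = 400,
                                            max_dist = 150000, layout = "grid4",
                                            k = NULL),
                               train = list(),
                               cluster = list(method = "louvain",
                                              k_neighbors = 15,
                                              resolution = 0.1, K = NULL)) {
  cfg <- list(seed = seed, sim = sim, preprocess = preprocess,
              graph = graph, train = train, cluster = cluster)
  class(cfg) <- "run_config"
  cfg
}

resolve_config <- function(path = NULL, seed = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (nm in names(user)) {
      if (is.list(cfg[[nm]]) && is.list(user[[nm]]))
        cfg[[nm]] <- utils::modifyList(cfg[[nm]], user[[nm]])
      else cfg[[nm]] <- user[[nm]]
    }
  }
  if (!is.null(seed)) cfg$seed <- seed
  cfg
}

write_resolved_config <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config_resolved.yaml"))
}

stage_log <- function(stage, t0) {
  message(sprintf("[%s] stage %s finished in %.1f s",
                  format(Sys.time(), "%H:%M:%S"), stage,
                  as.numeric(Sys.time()) - t0))
}

require_artifact <- function(path, stage) {
  if (!file.exists(path))
    stop("stage '", stage, "' requires missing artifact: ", path)
  path
}

#' Build the feature and spatial graphs for a dataset
#'
#' Orders the annotation to the concatenated feature list (modality 1
#' then modality 2) and builds both graphs the model consumes.
#'
#' @param dataset a [spatial_multiome()] dataset.
#' @param mode,bp_width,max_dist see [build_feature_graph()].
#' @param layout spatial layout; defaults to the dataset's coordinate
#'   layout hint.
#' @param k neighbor count for `layout = "knn"`.
#' @return list with `fg` (feature graph) and `sg` (spatial graph).
#' @export
dataset_graphs <- function(dataset, mode = "genomic", bp_width = 400,
                           max_dist = 150000, layout = NULL, k = NULL) {
  feats <- c(dataset$modality1$feature_ids, dataset$modality2$feature_ids)
  ann <- dataset$annotations
  ann <- ann[match(feats, ann$feature_id), , drop = FALSE]
  class(ann) <- c("feature_annotation", "data.frame")
  fg <- build_feature_graph(ann, mode = mode, bp_width = bp_width,
                            max_dist = max_dist)
  if (is.null(layout)) layout <- attr(dataset$coords, "layout")
  sg <- build_spatial_graph(dataset$coords, layout = layout, k = k)
  list(fg = fg, sg = sg)
}

build_graphs_from_dataset <- function(dataset, gcfg) {
  dataset_graphs(dataset, mode = gcfg$mode, bp_width = gcfg$bp_width,
                 max_dist = gcfg$max_dist, layout = gcfg$layout, k = gcfg$k)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (write a synthetic dataset), `preprocess`,
#' `graphs`, `train`, `links`, `cluster`, `evaluate`. Each stage consumes
#' the artifacts of its predecessors from `out` and writes its own there,
#' along with the resolved configuration.
#'
#' @param stage stage name.
#' @param config path to a YAML [default_run_config()] file, or a
#'   `run_config` list, or `NULL` for defaults.
#' @param out artifact directory.
#' @param seed overrides the configured seed when non-`NULL`.
#' @return invisibly, stage-specific outputs.
#' @export
run_stage <- function(stage = c("simulate", "preprocess", "graphs", "train",
                                "links", "cluster", "evaluate"),
                      config = NULL, out = "spagate_run", seed = NULL) {
  stage <- match.arg(stage)
  t0 <- as.numeric(Sys.time())
  cfg <- if (inherits(config, "run_config")) config else resolve_config(config, seed)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_resolved_config(cfg, out)

  load_raw <- function() {
    paths <- list(
      mod1_matrix = require_artifact(file.path(out, "data", "mod1_matrix.mtx"), stage),
      mod1_features = file.path(out, "data", "mod1_features.tsv"),
      mod1_barcodes = file.path(out, "data", "mod1_barcodes.tsv"),
      mod2_matrix = file.path(out, "data", "mod2_matrix.mtx"),
      mod2_features = file.path(out, "data", "mod2_features.tsv"),
      mod2_barcodes = file.path(out, "data", "mod2_barcodes.tsv"),
      genes = file.path(out, "data", "genes.tsv"),
      peaks = file.path(out, "data", "peaks.bed"),
      proteins = file.path(out, "data", "proteins.tsv"),
      coords = file.path(out, "data", "coords.csv"))
    if (!file.exists(paths$peaks)) paths$peaks <- NULL
    if (!file.exists(paths$proteins)) paths$proteins <- NULL
    mod2 <- if (identical(cfg$graph$mode, "coding")) "protein" else "atac"
    read_dataset(paths, layout = cfg$graph$layout,
                 modalities = c("rna", mod2))
  }
  load_pre <- function() {
    rds <- require_artifact(file.path(out, "preprocessed.rds"), stage)
    readRDS(rds)
  }

  res <- switch(stage,
    simulate = {
      sim_args <- utils::modifyList(cfg$sim, list(seed = cfg$seed))
      if (identical(cfg$graph$mode, "coding")) sim_args$modality2 <- "protein"
      sc <- do.call(sim_config, sim_args)
      sim <- simulate_tissue(sc)
      paths <- write_dataset(sim$dataset, file.path(out, "data"))
      write_tsv17(data.frame(spot_id = names(sim$truth$domains),
                             domain = as.integer(sim$truth$domains)),
                  file.path(out, "data", "domains_truth.tsv"))
      write_tsv17(sim$truth$links, file.path(out, "data", "links_truth.tsv"))
      sim
    },
    preprocess = {
      ds <- load_raw()
      pc <- do.call(preprocess_config, cfg$preprocess)
      pre <- preprocess_dataset(ds, pc)
      saveRDS(pre, file.path(out, "preprocessed.rds"))
      write_dataset(pre, file.path(out, "preprocessed"))
      pre
    },
    graphs = {
      pre <- load_pre()
      gs <- build_graphs_from_dataset(pre, cfg$graph)
      write_tsv17(gs$fg$edges, file.path(out, "feature_graph.tsv"))
      saveRDS(gs, file.path(out, "graphs.rds"))
      gs
    },
    train = {
      pre <- load_pre()
      gs <- readRDS(require_artifact(file.path(out, "graphs.rds"), stage))
      tc <- do.call(train_config, utils::modifyList(cfg$train, list(seed = cfg$seed)))
      fit <- train_model(pre, gs$fg, gs$sg, tc)
      saveRDS(fit[c("state", "config")], file.path(out, "checkpoint.rds"))
      jsonlite::write_json(list(seed = cfg$seed, iterations = tc$iterations,
                                final_loss = unname(fit$trace$total[tc$iterations])),
                           file.path(out, "checkpoint.json"), auto_unbox = TRUE)
      utils::write.csv(fit$trace, file.path(out, "loss_trace.csv"), row.names = FALSE)
      emb <- fuse_embeddings(fit$outputs$f, fit$outputs$g)
      rownames(emb) <- pre$modality1$spot_ids
      rownames(fit$outputs$f) <- rownames(fit$outputs$g) <- pre$modality1$spot_ids
      write_results(embeddings = emb, out_dir = out)
      write_results(embeddings = fit$outputs$f, out_dir = file.path(out, "embeddings_mod1"))
      write_results(embeddings = fit$outputs$g, out_dir = file.path(out, "embeddings_mod2"))
      fit
    },
    links = {
      pre <- load_pre()
      ckpt_path <- file.path(out, "checkpoint.rds")
      if (!file.exists(ckpt_path))
        stop("stage 'links' requires the trained checkpoint: ", ckpt_path)
      ckpt <- readRDS(ckpt_path)
      gs <- readRDS(require_artifact(file.path(out, "graphs.rds"), stage))
      fwd <- forward_dataset(pre, gs$fg, gs$sg, ckpt$state)
      links <- infer_links(ckpt$state, fwd, gs$fg, pre$annotations, seed = cfg$seed)
      write_results(links = links, out_dir = out)
      jsonlite::write_json(attr(links, "gmm")[c("theta", "means", "sds", "weights")],
                           file.path(out, "gmm_threshold.json"), auto_unbox = TRUE,
                           digits = NA)
      links
    },
    cluster = {
      emb <- read_embeddings(require_artifact(file.path(out, "embeddings.tsv"), stage))
      cc <- cfg$cluster
      cl <- if (identical(cc$method, "gmm"))
        cluster_gmm(emb, K = cc$K, seed = cfg$seed)
      else cluster_louvain(emb, k_neighbors = cc$k_neighbors,
                           resolution = cc$resolution, seed = cfg$seed)
      write_results(clusters = cl$labels, out_dir = out)
      cl
    },
    evaluate = {
      pre <- load_pre()
      cl <- utils::read.delim(require_artifact(file.path(out, "clusters.tsv"), stage))
      metrics <- list()
      truth_path <- file.path(out, "data", "domains_truth.tsv")
      if (file.exists(truth_path)) {
        tr <- utils::read.delim(truth_path)
        tr <- tr[match(cl$spot_id, tr$spot_id), ]
        metrics$clustering <- clustering_metrics(cl$cluster, tr$domain)
      }
      metrics$icc <- tryCatch(
        icc_combined(pre$modality1, pre$modality2, cl$cluster),
        error = function(e) {
          warning("ICC not computable: ", conditionMessage(e))
          NULL
        })
      links_path <- file.path(out, "links.tsv")
      bench_path <- file.path(out, "benchmark.tsv")
      if (file.exists(links_path) && file.exists(bench_path)) {
        lk <- utils::read.delim(links_path)
        bm <- utils::read.delim(bench_path)
        mode <- if ("pos" %in% names(bm)) "eqtl" else "enhancer"
        ev <- evaluate_links(lk, bm, mode)
        metrics$link_auroc <- ev$auroc
        utils::write.csv(roc_points(ev$table$score, ev$table$supported),
                         file.path(out, "roc_points.csv"), row.names = FALSE)
      }
      jsonlite::write_json(metrics, file.path(out, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      metrics
    })
  stage_log(stage, t0)
  invisible(res)
}

#' Run the full pipeline
#'
#' `simulate` (optional, when no input data is present in `out/data`) ->
#' `preprocess` -> `graphs` -> `train` -> `links` -> `cluster` ->
#' `evaluate`.
#'
#' @inheritParams run_stage
#' @param simulate whether to start from the synthetic generator.
#' @return invisibly, the `evaluate` stage metrics.
#' @export
run_pipeline <- function(config = NULL, out = "spagate_run", seed = NULL,
                         simulate = TRUE) {
  stages <- c(if (simulate) "simulate", "preprocess", "graphs", "train",
              "links", "cluster", "evaluate")
  res <- NULL
  for (st in stages) res <- run_stage(st, config = config, out = out, seed = seed)
  invisible(res)
}
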