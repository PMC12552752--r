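test_that("genomic distance is zero inside the peak and interval-anchored outside", {
  expect_equal(genomic_distance("chr1", 1000, 1500, "chr1", 1200), 0)
  expect_equal(genomic_distance("chr1", 1000, 1500, "chr1", 2000), 501)
  expect_equal(genomic_distance("chr1", 1000, 1500, "chr1", 500), 500)
  expect_true(is.na(genomic_distance("chr1", 1000, 1500, "chr2", 1200)))
  expect_error(genomic_distance("chr1", NA, 1500, "chr1", 10), "missing")
})

test_that("the distance prior kernel attains e at 0 and decays strictly in (1, e]", {
  expect_equal(distance_prior(0, 400), exp(1), tolerance = 1e-12)
  expect_equal(distance_prior(400, 400), exp(2^(-0.75)), tolerance = 1e-12)
  expect_equal(distance_prior(400, 400), 1.812312, tolerance = 1e-6)
  expect_equal(distance_prior(150000, 400), exp(376^(-0.75)), tolerance = 1e-12)
  expect_equal(distance_prior(150000, 400), 1.01178, tolerance = 1e-5)
  set.seed(1)
  d <- sort(c(0, runif(200, 0, 5e5)))
  pr <- distance_prior(d, 400)
  expect_true(all(diff(pr) < 0))
  expect_true(all(pr > 1 & pr <= exp(1)))
  expect_error(distance_prior(-1, 400), "negative")
})

test_that("the genomic feature graph keeps only pairs within the distance cutoff", {
  ann <- bind_annotations(
    feature_annotation("gene1", "gene", chrom = "chr1", tss = 0, strand = "+"),
    feature_annotation(c("near", "far", "other"), "peak",
                       chrom = c("chr1", "chr1", "chr2"),
                       start = c(10000, 200000, 100), end = c(10500, 200500, 600)))
  fg <- build_feature_graph(ann, mode = "genomic")
  expect_equal(nrow(fg$edges), 1)
  expect_setequal(c(fg$edges$feature1, fg$edges$feature2), c("near", "gene1"))
  # every node keeps a self-loop; genomic edge priors are in (1, e]
  self <- fg$ti == fg$si
  expect_setequal(fg$ti[self], seq_along(fg$nodes))
  expect_true(all(fg$edges$prior > 1 & fg$edges$prior <= exp(1)))
  # genomic self-loop prior uses distance 0
  expect_equal(fg$self_prior, rep(exp(1), 4))
})

test_that("edge priors match the kernel recomputed from the stored distances", {
  sim <- tiny_dataset(seed = 9)
  fg <- build_feature_graph(reorder_annotation(sim$dataset), mode = "genomic")
  expect_gt(nrow(fg$edges), 0)
  expect_equal(fg$edges$prior, distance_prior(fg$edges$dist, 400),
               tolerance = 1e-12)
  # connectivity is symmetric: each undirected edge appears in both directions
  key <- paste(fg$ti, fg$si)
  rkey <- paste(fg$si, fg$ti)
  expect_true(all(rkey %in% key))
})

test_that("protein coding-map mode links proteins to their coding genes with prior 1", {
  ann <- bind_annotations(
    feature_annotation(c("CD3E", "MS4A1"), "gene", chrom = "chr1",
                       tss = c(0, 1e6), strand = "+"),
    feature_annotation("CD3", "protein", coding_gene_ids = "CD3E"))
  fg <- build_feature_graph(ann, mode = "coding")
  expect_equal(nrow(fg$edges), 1)
  expect_equal(fg$edges$prior, 1)
  expect_equal(fg$self_prior, rep(1, 3))
  ann2 <- bind_annotations(
    feature_annotation("CD3E", "gene", chrom = "chr1", tss = 0, strand = "+"),
    feature_annotation("CD3", "protein", coding_gene_ids = "CD3E,CD3D"))
  expect_warning(fg2 <- build_feature_graph(ann2, mode = "coding"), "CD3D")
  expect_equal(nrow(fg2$edges), 1)
})

test_that("grid and hex layouts produce the expected neighborhood sizes", {
  co <- spot_coordinates(paste0("s", 1:9), rep(1:3, 3), rep(1:3, each = 3),
                         array_row = rep(1:3, each = 3), array_col = rep(1:3, 3),
                         layout = "grid4")
  g4 <- build_spatial_graph(co, "grid4")
  ns <- neighbor_sets(g4)
  center <- which(co$array_row == 2 & co$array_col == 2)
  expect_length(ns[[center]], 5)   # 4 neighbors + self
  corner <- which(co$array_row == 1 & co$array_col == 1)
  expect_length(ns[[corner]], 3)   # boundary spots have fewer
  g8 <- build_spatial_graph(co, "grid8")
  expect_length(neighbor_sets(g8)[[center]], 9)

  # hexagonal lattice in Visium-style array indexing: row parity offsets cols
  hx <- expand.grid(r = 1:5, c = 1:10)
  hx <- hx[(hx$r + hx$c) %% 2 == 0, ]
  coh <- spot_coordinates(paste0("h", seq_len(nrow(hx))),
                          hx$c, hx$r, array_row = hx$r, array_col = hx$c,
                          layout = "hex6")
  gh <- build_spatial_graph(coh, "hex6")
  interior <- which(hx$r == 3 & hx$c == 5)
  expect_length(neighbor_sets(gh)[[interior]], 7)  # 6 + self
})

test_that("spatial graphs are symmetric with unit diagonal; knn symmetrizes by union", {
  set.seed(6)
  co <- spot_coordinates(paste0("s", 1:20), runif(20), runif(20))
  gk <- build_spatial_graph(co, "knn", k = 3)
  S <- gk$S
  expect_true(Matrix::isSymmetric(S))
  expect_equal(unname(Matrix::diag(S)), rep(1, 20))
  expect_error(build_spatial_graph(co, "knn", k = 20), "smaller")
  co_dup <- spot_coordinates(c("a", "b"), 1:2, 1:2, array_row = c(1, 1),
                             array_col = c(1, 1), layout = "grid4")
  expect_error(build_spatial_graph(co_dup, "grid4"), "duplicate")
})
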