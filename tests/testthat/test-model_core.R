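two_node_graph <- function(dist = 0, bp_width = 400) {
  ann <- bind_annotations(
    feature_annotation("g", "gene", chrom = "chr1", tss = 0, strand = "+"),
    feature_annotation("p", "peak", chrom = "chr1", start = dist,
                       end = dist + 100))
  build_feature_graph(ann, mode = "genomic", bp_width = bp_width,
                      max_dist = 1e9)
}

test_that("cross attention with zero parameters reduces to the prior", {
  # one peak-gene edge at distance 0: prior e for edge and self -> 0.5 / 0.5
  fg <- two_node_graph(dist = 0)
  X <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(NULL, fg$nodes))
  at <- cross_attention(X, fg, v1 = c(0, 0), v2 = c(0, 0))
  expect_equal(unname(as.matrix(at$C)), matrix(0.5, 2, 2), tolerance = 1e-12)
})

test_that("a distant neighbor's prior shrinks its attention towards 1/(1+e)", {
  # as dist -> infinity the edge prior -> 1 while the self prior stays e
  ann <- bind_annotations(
    feature_annotation("g", "gene", chrom = "chr1", tss = 0, strand = "+"),
    feature_annotation("p", "peak", chrom = "chr1", start = 0, end = 100))
  fg <- build_feature_graph(ann, mode = "genomic")
  fg$prior[fg$ti != fg$si] <- 1  # limit case of the kernel
  X <- matrix(1, 3, 2, dimnames = list(NULL, fg$nodes))
  at <- cross_attention(X, fg, numeric(3), numeric(3))
  C <- as.matrix(at$C)
  expect_equal(C[1, 2], 1 / (1 + exp(1)), tolerance = 1e-6)
  expect_equal(C[1, 1], exp(1) / (1 + exp(1)), tolerance = 1e-6)
  expect_equal(C[1, 2], 0.2689, tolerance = 1e-3)
})

test_that("every attention neighborhood (cross and within) sums to one", {
  inp <- tiny_pipeline_input(seed = 5)
  st <- small_model(inp)
  fwd <- forward_dataset(inp$pre, inp$fg, inp$sg, st)
  expect_equal(unname(Matrix::rowSums(fwd$catt$C)),
               rep(1, length(inp$fg$nodes)), tolerance = 1e-6)
  for (k in 1:2)
    expect_equal(unname(Matrix::rowSums(fwd$enc[[k]]$att$P)),
                 rep(1, nrow(inp$pre$modality1$values)), tolerance = 1e-6)
  expect_true(all(fwd$catt$att >= 0 & fwd$catt$att <= 1))
})

test_that("cross encoding with self-loops only is the identity on nonnegative data", {
  ann <- bind_annotations(
    feature_annotation("g", "gene", chrom = "chr1", tss = 0, strand = "+"),
    feature_annotation("p", "peak", chrom = "chr2", start = 0, end = 100))
  fg <- build_feature_graph(ann, mode = "genomic")  # cross-chrom: no edge
  X <- matrix(c(1, 2, 0, 3), 2, 2, dimnames = list(NULL, fg$nodes))
  at <- cross_attention(X, fg, numeric(2), numeric(2))
  expect_equal(cross_encode(X, at), X, ignore_attr = TRUE, tolerance = 1e-12)
  # ReLU clips negatives in the encoder; ELU curves them in the decoder
  Xneg <- matrix(c(-1, 2, 0.5, 3), 2, 2)
  expect_equal(cross_encode(Xneg, at)[1, 1], 0)
  expect_equal(cross_decode(Xneg, at)[1, 1], exp(-1) - 1, tolerance = 1e-12)
})

test_that("two-node cross encoding averages profiles under equal attention", {
  fg <- two_node_graph(dist = 0)
  X <- cbind(c(2, 0), c(0, 2))
  colnames(X) <- fg$nodes
  at <- cross_attention(X, fg, numeric(2), numeric(2))  # all weights 0.5
  expect_equal(unname(cross_encode(X, at)), matrix(1, 2, 2), tolerance = 1e-12)
})

test_that("within-modality encoder behaves on a single isolated spot", {
  co <- spot_coordinates("s1", 0, 0, array_row = 1, array_col = 1,
                         layout = "grid4")
  sg <- build_spatial_graph(co, "grid4")
  x <- matrix(c(1, 2, 3), 1, 3)
  W1 <- diag(3); W2 <- diag(3)
  enc <- within_encode(x, sg, W1, numeric(3), numeric(3), W2)
  # softmax over {self} is 1; ELU is identity on nonnegative input
  expect_equal(enc$Z, x, ignore_attr = TRUE, tolerance = 1e-12)
  dec <- within_decode(enc$Z, sg, enc, W1, W2)
  expect_equal(dec$D0, x, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("spots with identical inputs and neighborhoods get identical outputs", {
  co <- spot_coordinates(c("a", "b"), c(0, 1), c(0, 0),
                         array_row = c(1, 1), array_col = c(1, 2),
                         layout = "grid4")
  sg <- build_spatial_graph(co, "grid4")
  x <- matrix(rep(c(1, 2), each = 2), 2, 2)
  set.seed(1)
  W1 <- matrix(rnorm(4), 2, 2); W2 <- matrix(rnorm(4), 2, 2)
  enc <- within_encode(x, sg, W1, rnorm(2), rnorm(2), W2)
  expect_equal(enc$Z[1, ], enc$Z[2, ], tolerance = 1e-12)
})

test_that("contrastive projection is linear and identity under identity maps", {
  set.seed(2)
  Z1 <- matrix(rnorm(12), 4, 3); Z2 <- matrix(rnorm(12), 4, 3)
  pj <- project_clip(Z1, Z2, diag(3), diag(3))
  expect_equal(pj$f, Z1)
  expect_equal(pj$g, Z2)
  M <- matrix(rnorm(9), 3, 3)
  expect_equal(project_clip(3 * Z1, Z2, M, M)$f,
               3 * project_clip(Z1, Z2, M, M)$f, tolerance = 1e-12)
  expect_equal(project_clip(Z1 * 0, Z2, M, M)$f, matrix(0, 4, 3))
})

test_that("the forward pass is deterministic and shape-preserving", {
  inp <- tiny_pipeline_input(seed = 11)
  st <- small_model(inp)
  f1 <- forward_dataset(inp$pre, inp$fg, inp$sg, st)
  f2 <- forward_dataset(inp$pre, inp$fg, inp$sg, st)
  expect_identical(f1$f, f2$f)
  expect_identical(f1$Xhat1, f2$Xhat1)
  expect_equal(dim(f1$Xhat1), dim(as.matrix(inp$pre$modality1$values)))
  expect_equal(dim(f1$Xhat2), dim(as.matrix(inp$pre$modality2$values)))
  expect_equal(ncol(f1$Z1), st$hidden[2])
  # loss is finite on the synthetic fixture
  expect_true(is.finite(reconstruction_loss(
    as.matrix(inp$pre$modality1$values), as.matrix(inp$pre$modality2$values),
    f1$Xhat1, f1$Xhat2)))
  expect_true(is.finite(clip_loss(f1$f, f1$g)))
})

test_that("no decoder parameters exist: decoding reuses encoder objects", {
  st <- init_model(4, 3, 3, hidden = c(4, 2), seed = 0)
  expect_setequal(names(st$params),
                  c("v1", "v2", "W1_1", "vself_1", "vnei_1", "W2_1",
                    "W1_2", "vself_2", "vnei_2", "W2_2", "M1", "M2"))
  inp <- tiny_pipeline_input(seed = 13)
  st <- small_model(inp)
  fwd <- forward_dataset(inp$pre, inp$fg, inp$sg, st)
  # decoder attention matrices are the encoder's, bit for bit
  recon <- cross_decode(fwd$Xtld, fwd$catt)
  expect_equal(cbind(fwd$Xhat1, fwd$Xhat2), recon, ignore_attr = TRUE)
})
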