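test_that("a lone peak-gene pair at distance zero gets attention one half", {
  ann <- bind_annotations(
    feature_annotation("gene1", "gene", chrom = "chr1", tss = 50, strand = "+"),
    feature_annotation("peak1", "peak", chrom = "chr1", start = 0, end = 100))
  fg <- build_feature_graph(ann, mode = "genomic")
  X <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(NULL, fg$nodes))
  st <- init_model(2, 1, 1, hidden = c(2, 2), seed = 0)
  st$trained <- TRUE
  at <- cross_attention(X, fg, st$params$v1, st$params$v2)
  tb <- extract_pair_scores(st, list(catt = at), fg)
  expect_equal(nrow(tb), 1)
  expect_equal(tb$att, 0.5, tolerance = 1e-12)
  expect_equal(tb$dist, 0)
  # the peak's full neighborhood (gene + self) sums to one
  peak_row <- which(fg$nodes == "peak1")
  expect_equal(sum(at$att[at$ti == peak_row]), 1, tolerance = 1e-12)
  st$trained <- FALSE
  expect_error(extract_pair_scores(st, list(catt = at), fg), "untrained")
})

test_that("peaks with no gene within reach are absent from the score table", {
  ann <- bind_annotations(
    feature_annotation("gene1", "gene", chrom = "chr1", tss = 0, strand = "+"),
    feature_annotation(c("near", "far"), "peak", chrom = "chr1",
                       start = c(1000, 4e5), end = c(1500, 4e5 + 500)))
  fg <- build_feature_graph(ann, mode = "genomic")
  X <- matrix(1, 2, 3, dimnames = list(NULL, fg$nodes))
  st <- init_model(2, 1, 2, hidden = c(2, 2), seed = 0)
  st$trained <- TRUE
  tb <- extract_pair_scores(st, list(catt = cross_attention(X, fg, numeric(2), numeric(2))), fg)
  expect_identical(tb$peak_id, "near")
})

test_that("unit-interval rescaling is linear, endpoint-exact and order-preserving", {
  expect_equal(rescale_unit_interval(c(0.1, 0.3, 0.5)), c(0, 0.5, 1))
  set.seed(8)
  v <- runif(50)
  s <- rescale_unit_interval(v)
  expect_equal(s[which.min(v)], 0)
  expect_equal(s[which.max(v)], 1)
  expect_identical(order(s), order(v))
  expect_error(rescale_unit_interval(rep(0.2, 10)), "constant")
  expect_error(rescale_unit_interval(0.5), "at least 2")
})

test_that("the mixture threshold is the midpoint for a symmetric mixture", {
  # equal weights and variances force the density crossing at the midpoint
  set.seed(0)
  x <- c(rnorm(500, 0.2, 0.05), rnorm(500, 0.8, 0.05))
  fit <- gmm_threshold(x, seed = 0)
  expect_equal(fit$theta, 0.5, tolerance = 0.02)
  expect_lt(fit$means[1], fit$theta)
  expect_gt(fit$means[2], fit$theta)
  expect_equal(fit$means, c(0.2, 0.8), tolerance = 0.02)
})

test_that("the mixture threshold errors on degenerate inputs", {
  expect_error(gmm_threshold(runif(10), seed = 0), "at least 50")
  # extreme weight imbalance: one component swallows the data and no
  # density crossing exists between the means
  set.seed(2)
  x <- c(rnorm(2000, 0.5, 0.2), 0.95)
  expect_error(gmm_threshold(x, seed = 0), "intersection|converge")
})

test_that("link calling thresholds, sorts, and is monotone in theta", {
  tb <- data.frame(peak_id = c("p1", "p2", "p3"), gene_id = c("g1", "g2", "g3"),
                   att = c(0.2, 0.6, 0.4))
  out <- call_links(tb, 0.5)
  expect_equal(out$score, c(1, 0.5, 0))
  expect_equal(out$called, c(TRUE, TRUE, FALSE))
  out0 <- call_links(tb, 0)
  expect_true(all(out0$called))
  expect_error(call_links(tb, 1.5), "theta")
  # lowering theta never removes a call
  for (th in c(0.9, 0.6, 0.3)) {
    hi <- call_links(tb, th)
    lo <- call_links(tb, th - 0.2)
    expect_true(all(hi$peak_id[hi$called] %in% lo$peak_id[lo$called]))
  }
})

test_that("AUROC matches the exhaustive pairwise oracle, ties included", {
  expect_equal(auroc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  expect_equal(auroc(c(0.9, 0.8, 0.1), c(0, 0, 1)), 0)
  expect_equal(auroc(rep(0.5, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  set.seed(10)
  for (rep_i in 1:25) {
    n <- sample(4:20, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    lb <- sample(c(0, 1), n, replace = TRUE)
    if (sum(lb) %in% c(0, n)) next
    expect_equal(auroc(sc, lb), auroc_bruteforce(sc, lb), tolerance = 1e-12)
  }
  expect_error(auroc(c(1, 2), c(1, 1)), "positive and negative")
})

test_that("benchmark evaluation supports eQTL loci and enhancer intervals", {
  tb <- data.frame(peak_id = c("p1", "p2", "p3"),
                   gene_id = c("g1", "g1", "g2"),
                   score = c(0.9, 0.2, 0.5),
                   chrom = "chr1",
                   start = c(100, 1000, 2000),
                   end = c(200, 1100, 2100))
  # eQTL mode: locus 150 falls inside p1 only and is associated with g1
  bench <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      pos = c(150, 5000))
  ev <- evaluate_links(tb, bench, mode = "eqtl")
  expect_equal(ev$table$supported, c(TRUE, FALSE, FALSE))
  expect_equal(ev$auroc, 1)
  # enhancer mode: interval overlapping p3, annotated to g2
  bench2 <- data.frame(gene_id = c("g2", "g1"), chrom = "chr1",
                       start = c(2050, 9000), end = c(2060, 9100))
  ev2 <- evaluate_links(tb, bench2, mode = "enhancer")
  expect_true(ev2$table$supported[ev2$table$peak_id == "p3"])
  # a locus inside a peak linked to a different gene does not support it
  bench3 <- data.frame(gene_id = "g9", chrom = "chr1", pos = 150)
  expect_error(evaluate_links(tb, bench3, "eqtl"), "no link gene")
})

test_that("planted links score higher than decoys on average after training", {
  acc <- acceptance_fit()
  links <- infer_links(acc$fit$state, acc$fit$outputs, acc$fg,
                       acc$pre$annotations, seed = 0)
  planted <- paste(links$peak_id, links$gene_id) %in%
    paste(acc$sim$truth$links$peak_id, acc$sim$truth$links$gene_id)
  expect_gt(mean(links$score[planted]), mean(links$score[!planted]))
  # theta sits strictly between the fitted component means
  gmm <- attr(links, "gmm")
  expect_true(gmm$means[1] < gmm$theta && gmm$theta < gmm$means[2])
})

test_that("AUROC agrees with the pROC reference implementation", {
  set.seed(21)
  sc <- runif(40); lb <- sample(c(0, 1), 40, replace = TRUE)
  expect_equal(auroc(sc, lb),
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                              direction = "<",
                                              levels = c(0, 1)))),
               tolerance = 1e-12)
})

test_that("the hand-written EM agrees with mclust on a clear mixture", {
  set.seed(22)
  x <- c(rnorm(400, 0.25, 0.04), rnorm(600, 0.75, 0.06))
  fit <- gmm_threshold(x, seed = 0)
  mc <- mclust::densityMclust(x, G = 2, modelNames = "V", verbose = FALSE,
                              plot = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
})

test_that("ROC points start at the origin, end at (1, 1) and integrate to the AUROC", {
  set.seed(30)
  sc <- runif(25); lb <- sample(c(0, 1), 25, replace = TRUE)
  rp <- roc_points(sc, lb)
  expect_equal(rp$fpr[1], 0); expect_equal(rp$tpr[1], 0)
  expect_equal(rp$fpr[nrow(rp)], 1); expect_equal(rp$tpr[nrow(rp)], 1)
  expect_true(all(diff(rp$fpr) >= 0) && all(diff(rp$tpr) >= 0))
  trap <- sum(diff(rp$fpr) * (utils::head(rp$tpr, -1) + utils::tail(rp$tpr, -1)) / 2)
  expect_equal(trap, auroc(sc, lb), tolerance = 1e-12)
})
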