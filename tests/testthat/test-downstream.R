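test_that("embedding fusion is the elementwise midpoint", {
  set.seed(1)
  f <- matrix(rnorm(20), 5, 4)
  expect_equal(fuse_embeddings(f, f), f)
  expect_equal(fuse_embeddings(f, -f), matrix(0, 5, 4))
  expect_equal(fuse_embeddings(matrix(c(1, 0), 1, 2), matrix(c(0, 1), 1, 2)),
               matrix(0.5, 1, 2))
  expect_error(fuse_embeddings(f, f[1:3, ]), "shape")
})

blob_data <- function(n_per = 20, sep = 20, seed = 3) {
  set.seed(seed)
  Z <- rbind(matrix(rnorm(n_per * 2), n_per, 2),
             matrix(rnorm(n_per * 2) + sep, n_per, 2))
  rownames(Z) <- paste0("s", seq_len(2 * n_per))
  list(Z = Z, truth = rep(1:2, each = n_per))
}

test_that("well-separated blobs are recovered by Louvain and GMM clustering", {
  bd <- blob_data()
  cl <- cluster_louvain(bd$Z, k_neighbors = 5, seed = 0)
  expect_equal(length(unique(cl$labels)), 2)
  expect_equal(clustering_metrics(cl$labels, bd$truth)$ARI, 1)
  cl2 <- cluster_louvain(bd$Z, k_neighbors = 5, seed = 0)
  expect_identical(cl$labels, cl2$labels)
  expect_error(cluster_louvain(bd$Z, k_neighbors = 40), "k_neighbors")

  cg <- cluster_gmm(bd$Z, K = 2, seed = 0)
  expect_equal(clustering_metrics(cg$labels, bd$truth)$ARI, 1)
  expect_error(cluster_gmm(bd$Z, K = 1), "K")
  expect_identical(cluster_gmm(bd$Z, K = 2, seed = 0)$labels, cg$labels)
  # labels are contiguous codes from zero
  expect_setequal(unique(cl$labels), c(0L, 1L))
})

test_that("rank-sum marker test matches exact enumeration and handles ties", {
  x <- cbind(feat = c(1, 2, 3, 10, 11, 12))
  rownames(x) <- paste0("s", 1:6)
  labels <- c("a", "a", "a", "b", "b", "b")
  deg <- rank_deg_wilcoxon(x, labels)
  # most extreme of the C(6,3) = 20 assignments, two-sided: p = 2/20
  expect_equal(deg$p[deg$cluster == "a"], 0.1, tolerance = 1e-12)
  expect_equal(deg$p[deg$cluster == "a"],
               wilcox_exact_p(c(1, 2, 3), c(10, 11, 12)), tolerance = 1e-12)
  # identical groups: p = 1 under tie handling
  x2 <- cbind(feat = rep(c(5, 5, 5), 2))
  deg2 <- suppressWarnings(rank_deg_wilcoxon(x2, labels))
  expect_equal(deg2$p, rep(1, 2))
  # BH never lowers a raw p
  set.seed(4)
  x3 <- matrix(rnorm(60), 6, 10, dimnames = list(NULL, paste0("f", 1:10)))
  deg3 <- suppressWarnings(rank_deg_wilcoxon(x3, labels))
  expect_true(all(deg3$p_adj >= deg3$p - 1e-12))
  expect_true(all(deg3$p_adj <= 1))
  expect_error(rank_deg_wilcoxon(x3, c("a", rep("b", 5))), "singleton")
})

test_that("rank-sum p-values match exact enumeration for small random groups", {
  set.seed(7)
  for (i in 1:10) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    v <- sample(1:50, nx + ny)  # all distinct -> exact test
    x <- v[seq_len(nx)]; y <- v[nx + seq_len(ny)]
    p_pkg <- stats::wilcox.test(x, y)$p.value
    expect_equal(p_pkg, wilcox_exact_p(x, y), tolerance = 1e-10)
  }
})

test_that("clustering metrics match hand values and the pair-counting oracle", {
  expect_equal(clustering_metrics(c(1, 2, 1, 2), c(1, 2, 1, 2))$ARI, 1)
  # relabeling leaves every metric unchanged
  m1 <- clustering_metrics(c(1, 1, 2, 2, 3), c(2, 2, 3, 3, 1))
  expect_equal(m1$ARI, 1)
  expect_equal(m1$NMI, 1)
  # the classic anti-correlated 2x2 case
  expect_equal(clustering_metrics(c(1, 1, 2, 2), c(1, 2, 1, 2))$ARI, -0.5)
  set.seed(5)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    got <- clustering_metrics(a, b)
    oracle <- ari_bruteforce(a, b)
    expect_equal(got$ARI, oracle$ARI, tolerance = 1e-12)
    expect_equal(got$RI, oracle$RI, tolerance = 1e-12)
    # cross-check against the reference implementation
    expect_equal(got$ARI, mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    # permutation of label codes changes nothing
    perm <- sample(3)
    expect_equal(clustering_metrics(perm[a], b)$AMI, got$AMI, tolerance = 1e-12)
  }
  expect_error(clustering_metrics(1:3, 1:4), "length")
})

test_that("metric values stay in their documented ranges on random inputs", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(6:15, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    m <- clustering_metrics(a, b)
    expect_true(all(unlist(m[c("RI", "NMI", "homogeneity", "completeness",
                                "v_measure", "FMI")]) >= 0))
    expect_true(all(unlist(m) <= 1 + 1e-12))
  }
})

test_that("ICC is one for pure clusters, near zero for random labels, zero when degenerate", {
  x <- cbind(v = c(5, 5, 1, 1))
  expect_equal(icc_score(x, c("a", "a", "b", "b"))$icc, 1)
  set.seed(11)
  n <- 1000
  xr <- cbind(v = rnorm(n))
  icc_r <- icc_score(xr, sample(rep(1:4, each = n / 4)))$icc
  expect_lt(abs(icc_r), 0.1)
  xc <- cbind(v = rep(3, 6))
  expect_warning(icc0 <- icc_score(xc, rep(1:2, each = 3))$icc, "degenerate")
  expect_equal(icc0, 0)
  expect_error(icc_score(x, c("a", "b", "b", "b")), ">= 2")
  # combined score is the unweighted mean of the modalities
  set.seed(12)
  m1 <- matrix(rnorm(40), 10, 4); m2 <- matrix(rnorm(20), 10, 2)
  lab <- rep(1:2, each = 5)
  cmb <- icc_combined(m1, m2, lab)
  expect_equal(cmb$combined, (cmb$icc1 + cmb$icc2) / 2)
})
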