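test_that("the discriminant ratio matches hand-computed scatter traces", {
  # two 1-D classes {0,1} and {3,4}: S_B trace 9, S_W trace 1
  expect_equal(
    fisher_discriminant_ratio(matrix(c(0, 1, 3, 4)), c("a", "a", "b", "b")),
    9
  )
  # identical class means: no between-class scatter
  expect_equal(
    fisher_discriminant_ratio(matrix(c(0, 1, 0, 1)), c("a", "a", "b", "b")),
    0
  )
  expect_error(
    fisher_discriminant_ratio(matrix(c(1, 1, 2, 2)), c("a", "a", "b", "b")),
    "degenerate"
  )
  expect_error(fisher_discriminant_ratio(matrix(1:4), c("a", "a", "a", "a")),
               "two classes")
})

test_that("the discriminant ratio is translation and scale invariant", {
  set.seed(42)
  X <- matrix(rnorm(60), nrow = 12)
  lab <- rep(letters[1:3], each = 4)
  base <- fisher_discriminant_ratio(X, lab)
  shift <- sweep(X, 2, c(5, -3, 100, 0.2, 7), "+")
  expect_equal(fisher_discriminant_ratio(shift, lab), base)
  expect_equal(fisher_discriminant_ratio(X * 3.7, lab), base)
})

test_that("pearson correlation matches hand computation and bounds", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, 2 * x + 1), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  # hand: S_xy = 4.5, S_xx = 5, S_yy = 4.75 -> r = 4.5 / sqrt(23.75)
  expect_equal(pearson_correlation(x, c(1, 2, 2, 4)), 4.5 / sqrt(23.75),
               tolerance = 1e-12)
  expect_error(pearson_correlation(x, rep(1, 4)), "constant")
  expect_error(pearson_correlation(x, 1:3), "equal length")
  set.seed(1)
  for (i in 1:20) {
    r <- pearson_correlation(rnorm(10), rnorm(10))
    expect_true(r >= -1 && r <= 1)
  }
})

test_that("mean-scalarized correlation is exact for unclipped inputs", {
  panel <- generate_odor_panel(6, 16, seed = 2)
  concs <- c(0.4, 0.6, 0.8, 1.0, 1.2, 1.4)
  # build the unclipped response by hand (S * C with no ceiling)
  R <- do.call(rbind, lapply(1:6, function(i) {
    t(vapply(concs, function(co) panel[i, ] * co, numeric(16)))
  }))
  odor <- rep(LETTERS[1:6], each = 6)
  conc <- rep(concs, 6)
  cc <- concentration_correlation(R, odor, conc, method = "mean")
  expect_equal(unname(cc$per_odor), rep(1, 6))
  expect_equal(cc$sd, 0)
})

test_that("pooled correlation penalizes across-neuron heterogeneity", {
  concs <- rep(c(1, 2, 3), 2)
  odor <- rep("A", 6)
  # homogeneous population tracking concentration: pooled r = 1
  X_hom <- outer(concs, c(1, 1, 1))
  hom <- concentration_correlation(X_hom, odor, concs, method = "pooled")
  expect_equal(unname(hom$per_odor), 1)
  # heterogeneous gains leave pooled r below 1 although each neuron
  # is perfectly correlated with concentration
  X_het <- outer(concs, c(1, 10, 25))
  het <- concentration_correlation(X_het, odor, concs, method = "pooled")
  expect_lt(het$mean, 1)
  expect_equal(
    unname(het$per_odor),
    pearson_correlation(as.vector(X_het), rep(concs, 3))
  )
})

test_that("constant responses are flagged and excluded", {
  X <- rbind(matrix(1, 3, 4), outer(1:3, 1:4))
  odor <- rep(c("A", "B"), each = 3)
  conc <- rep(1:3, 2)
  cc <- concentration_correlation(X, odor, conc)
  expect_equal(cc$excluded, "A")
  expect_false(is.na(cc$mean))
  expect_error(
    concentration_correlation(matrix(1, 3, 4), rep("A", 3), 1:3),
    "degenerate"
  )
  expect_error(
    concentration_correlation(X, odor, rep(1, 6)),
    "distinct concentrations"
  )
})

test_that("negating the response negates every per-odor coefficient", {
  set.seed(3)
  X <- matrix(runif(48), nrow = 12)
  odor <- rep(c("A", "B"), each = 6)
  conc <- rep(1:6, 2)
  for (m in c("pooled", "mean")) {
    a <- concentration_correlation(X, odor, conc, method = m)$per_odor
    b <- concentration_correlation(-X, odor, conc, method = m)$per_odor
    expect_equal(b, -a)
  }
})

test_that("PCA matches an independent SVD oracle", {
  set.seed(7)
  X <- matrix(rnorm(20 * 6), nrow = 20)
  pc <- pca_scores(X)
  # oracle: scores of centered data from the SVD
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  oracle <- sv$u %*% diag(sv$d)
  for (j in seq_len(ncol(pc$scores))) {
    expect_true(
      isTRUE(all.equal(pc$scores[, j], oracle[, j], tolerance = 1e-8,
                       check.attributes = FALSE)) ||
      isTRUE(all.equal(pc$scores[, j], -oracle[, j], tolerance = 1e-8,
                       check.attributes = FALSE))
    )
  }
  expect_equal(pc$var_explained_all,
               sv$d^2 / sum(sv$d^2), tolerance = 1e-10)
  expect_equal(sum(pc$var_explained_all), 1, tolerance = 1e-9)
  expect_true(all(diff(pc$var_explained_all) <= 1e-12))
  # score columns are mutually orthogonal
  G <- crossprod(pc$scores)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)
})

test_that("rank-1 data loads entirely on the first component", {
  X <- outer(1:10, c(2, -1, 0.5))
  pc <- pca_scores(X, n_components = 1)
  expect_equal(pc$var_explained_all[1], 1)
  expect_error(pca_scores(X, n_components = 5), "n_components")
})

test_that("bisecting k-means recovers a planted two-blob partition", {
  set.seed(11)
  blob1 <- matrix(rnorm(6 * 2, mean = 0, sd = 0.3), ncol = 2)
  blob2 <- matrix(rnorm(6 * 2, mean = 8, sd = 0.3), ncol = 2)
  X <- rbind(blob1, blob2)
  dend <- hierarchical_kmeans(X, seed = 5)
  expect_equal(length(dend$labels), 12)
  top <- cut_clusters(dend, 2)
  oracle <- brute_force_best_bipartition(X)
  expect_setequal(which(top == top[oracle[1]]), oracle)
})

test_that("dendrograms are deterministic and Newick-exportable", {
  set.seed(13)
  X <- matrix(rnorm(18 * 3), nrow = 18)
  d1 <- hierarchical_kmeans(X, seed = 2)
  d2 <- hierarchical_kmeans(X, seed = 2)
  expect_identical(d1$newick, d2$newick)
  phy <- as_phylo(d1)
  expect_equal(ape::Ntip(phy), 18)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(d1, f)
  expect_equal(ape::Ntip(ape::read.tree(f)), 18)
})

test_that("duplicated points merge at height zero", {
  X <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5.1, 5))
  dend <- hierarchical_kmeans(X, seed = 1)
  # the node splitting the two duplicates has height 0
  dup_nodes <- which(vapply(dend$members, function(m) {
    setequal(m, c(1, 2))
  }, logical(1)))
  expect_true(length(dup_nodes) >= 1)
  expect_equal(dend$heights[dup_nodes], 0)
  # every partition level keeps exactly n leaves
  expect_equal(length(cut_clusters(dend, 4)), 4)
})

test_that("each partition level adds exactly one cluster", {
  set.seed(17)
  X <- matrix(rnorm(20), nrow = 10)
  dend <- hierarchical_kmeans(X, seed = 3)
  for (k in 1:10) {
    expect_equal(length(unique(cut_clusters(dend, k))), k)
  }
  # successive partitions refine each other
  for (k in 2:10) {
    prev <- cut_clusters(dend, k - 1)
    cur <- cut_clusters(dend, k)
    tab <- table(prev, cur)
    expect_true(all(colSums(tab > 0) == 1))
  }
})
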