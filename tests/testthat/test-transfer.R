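test_that("gene intersection preserves signature order and counts", {
  sigs <- list(cluster1 = c("g3", "g1"), cluster2 = c("g7", "g5"))
  shared <- intersect_genes(sigs, c("g1", "g5", "g3", "g9"))
  expect_identical(as.character(shared), c("g3", "g1", "g5"))
  expect_equal(unname(attr(shared, "per_cluster_counts")), c(2, 1))
  # superset target retains the full signature
  full <- intersect_genes(sigs, paste0("g", 1:10))
  expect_identical(as.character(full), c("g3", "g1", "g7", "g5"))
  expect_error(intersect_genes(sigs, c("x1", "x2")), "no signature genes")
})

test_that("intersection size tracks the gene-keep fraction", {
  d <- generate_discovery(small_config(seed = 3))
  v <- generate_validation(d, 0.6, 0, n_samples = 20, seed = 8)
  n_sig <- length(unlist(d$truth$signatures))
  got <- length(intersect_genes(d$truth$signatures, v))
  ci <- qbinom(c(0.0005, 0.9995), n_sig, 0.6)
  expect_gte(got, ci[1])
  expect_lte(got, ci[2])
})

test_that("LDA separates two well-separated 1-D classes at the midpoint", {
  set.seed(5)
  x <- matrix(c(rnorm(50, 0), rnorm(50, 10)), nrow = 1,
              dimnames = list("g1", NULL))
  labels <- rep(c("a", "b"), each = 50)
  m <- fit_lda(x, labels)
  res <- assign_clusters(m, x)
  expect_equal(mean(res$labels == labels), 1)
  grid <- matrix(seq(0, 10, by = 0.05), nrow = 1,
                 dimnames = list("g1", NULL))
  post <- assign_clusters(m, grid)$posteriors
  boundary <- grid[1, which.min(abs(post[, "a"] - 0.5))]
  expect_gt(boundary, 4); expect_lt(boundary, 6)
})

test_that("identical class distributions give posteriors near the priors", {
  set.seed(6)
  x <- matrix(rnorm(3 * 600), nrow = 3,
              dimnames = list(paste0("g", 1:3), NULL))
  labels <- rep(c("a", "b"), times = c(400, 200))
  m <- fit_lda(x, labels)
  post <- assign_clusters(m, x)$posteriors
  expect_equal(unname(colMeans(post)), unname(m$priors), tolerance = 0.1)
})

test_that("perfect collinearity is absorbed by the ridge", {
  set.seed(7)
  base <- rbind(g1 = rnorm(40, rep(c(0, 4), each = 20)))
  x <- rbind(base, g2 = base[1, ])     # exact duplicate gene
  expect_silent(m <- fit_lda(x, rep(c("a", "b"), each = 20)))
  expect_gt(min(eigen(m$pooled_covariance)$values), 0)
})

test_that("class size guards trigger", {
  x <- matrix(rnorm(8), 2, 4, dimnames = list(c("g1", "g2"), NULL))
  expect_error(fit_lda(x, c("a", "a", "a", "b")), "at least 2 samples")
  expect_error(fit_lda(x, rep("a", 4)), "at least 2 classes")
})

test_that("posteriors agree with the reference LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(8)
  n <- 150
  x <- t(rbind(MASS::mvrnorm(n, c(0, 0, 0), diag(3)),
               MASS::mvrnorm(n, c(2, 1, 0), diag(3))))
  rownames(x) <- paste0("g", 1:3)
  labels <- rep(c("a", "b"), each = n)
  ours <- assign_clusters(fit_lda(x, labels, lambda = 1e-10), x)$posteriors
  ref <- predict(MASS::lda(t(x), grouping = labels))$posterior
  expect_equal(unname(ours), unname(ref), tolerance = 1e-4)
})

test_that("posterior rows always sum to one and labels match the argmax", {
  fx <- fixture_discovery()
  v <- generate_validation(fx$data, 0.6, 0.1, n_samples = 50, seed = 4)
  shared <- intersect_genes(fx$model$informative_genes, v)
  m <- fit_lda(fx$prep$matrix$values[shared, ], fx$model$sample_labels)
  res <- assign_clusters(m, vst_transform(v)$values)
  expect_equal(unname(rowSums(res$posteriors)), rep(1, 50),
               tolerance = 1e-9)
  expect_identical(unname(res$labels),
                   colnames(res$posteriors)[max.col(res$posteriors,
                                                    ties.method = "first")])
  # transfer is invariant to gene order in the target
  vv <- vst_transform(v)$values
  res2 <- assign_clusters(m, vv[rev(rownames(vv)), ])
  expect_identical(res$labels, res2$labels)
  expect_equal(res$posteriors, res2$posteriors)
  # missing genes are named
  expect_error(assign_clusters(m, vv[-match(shared[1], rownames(vv)), ]),
               shared[1])
})

test_that("one-hot posteriors give an identity average-posterior matrix", {
  set.seed(9)
  centers <- matrix(c(0, 0, 40, 0, 0, 40), 2)
  x <- matrix(NA_real_, 2, 60, dimnames = list(c("g1", "g2"), NULL))
  labels <- rep(1:3, each = 20)
  for (i in 1:60) x[, i] <- rnorm(2, centers[, labels[i]], 0.5)
  res <- assign_clusters(fit_lda(x, labels), x)
  expect_equal(unname(res$avg_posterior), diag(3), tolerance = 1e-6)
})

test_that("bootstrap stability is reproducible and bounded", {
  fx <- fixture_discovery()
  v <- generate_validation(fx$data, 0.6, 0.1, n_samples = 60, seed = 4)
  shared <- intersect_genes(fx$model$informative_genes, v)
  m <- fit_lda(fx$prep$matrix$values[shared, ], fx$model$sample_labels)
  vv <- vst_transform(v)$values
  b1 <- bootstrap_stability(m, vv, n_iterations = 50, seed = 11)
  b2 <- bootstrap_stability(m, vv, n_iterations = 50, seed = 11)
  expect_identical(b1$accuracy, b2$accuracy)
  expect_identical(b1$silhouette, b2$silhouette)
  expect_true(all(b1$silhouette >= -1 & b1$silhouette <= 1))
  expect_true(all(b1$accuracy >= 0 & b1$accuracy <= 1))
  expect_lte(b1$accuracy_ci[1], b1$accuracy_ci[2])
  expect_lte(b1$silhouette_ci[1], b1$silhouette_ci[2])
})

test_that("transfer accuracy is monotone in the planted effect size", {
  acc <- vapply(c(0.5, 1, 2), function(l2fc) {
    cfg <- small_config(seed = 37, log2_fold_change = l2fc,
                        n_samples = 90)
    d <- generate_discovery(cfg)
    v <- generate_validation(d, 0.6, 0, n_samples = 90, seed = 2)
    sig <- intersect_genes(d$truth$signatures, v)
    m <- fit_lda(vst_transform(d)$values[sig, ], d$truth$labels)
    res <- assign_clusters(m, vst_transform(v)$values)
    mean(as.integer(res$labels) == v$truth$labels)
  }, numeric(1))
  expect_false(is.unsorted(acc))
  expect_lt(acc[1], 1)
})

test_that("reverse validation is self-consistent and permutation invariant", {
  fx <- fixture_discovery()
  rv <- reverse_validate(fx$data, fx$data$truth$labels, n_top = 300,
                         n_runs = 4, max_iter = 300, seed = 13)
  expect_equal(unname(rv$overlap), rep(1, 3))
  perm <- c(2L, 3L, 1L)
  rv2 <- reverse_validate(fx$data, perm[fx$data$truth$labels], n_top = 300,
                          n_runs = 4, max_iter = 300, seed = 13)
  expect_equal(sort(rv2$overlap), sort(rv$overlap))
})
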