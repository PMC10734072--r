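test_that("stratified folds partition the data and preserve strata", {
  y <- rep(c("a", "b"), each = 50)
  folds <- stratified_folds(y, 10, seed = 1)
  expect_length(folds, 10)
  for (f in folds) expect_equal(as.vector(table(y[f])), c(5, 5))
  expect_setequal(unlist(folds), seq_along(y))
  expect_equal(sum(lengths(folds)), length(y))

  # cohort-like 60/59 sizes: fold sizes differ by at most one sample,
  # per-fold class counts within one of the global proportion
  y2 <- rep(c("case", "ctrl"), times = c(60, 59))
  folds2 <- stratified_folds(y2, 10, seed = 2)
  expect_lte(diff(range(lengths(folds2))), 1)
  for (f in folds2) {
    tab <- table(factor(y2[f], levels = c("case", "ctrl")))
    expect_lte(abs(tab[1] - 6), 1)
    expect_lte(abs(tab[2] - 5.9), 1)
  }
  expect_error(stratified_folds(rep(c("a", "b"), c(5, 50)), 10, seed = 1),
               "smaller than n_folds")
})

test_that("SMOTE balances classes with convex-combination points", {
  set.seed(3)
  x_min <- matrix(rnorm(10 * 4), 10, 4)
  x_maj <- matrix(rnorm(50 * 4, 3), 50, 4)
  x <- rbind(x_min, x_maj)
  y <- rep(c("min", "maj"), c(10, 50))
  out <- smote_oversample(x, y, seed = 5)
  expect_equal(as.vector(table(out$y)), c(50, 50))
  synth <- out$x[-seq_len(60), , drop = FALSE]
  # every synthetic point lies on a segment between two minority points
  for (i in seq_len(nrow(synth))) {
    p <- synth[i, ]
    resid <- Inf
    for (a in seq_len(10)) for (b in seq_len(10)) {
      if (a == b) next
      v <- x_min[b, ] - x_min[a, ]
      u <- sum((p - x_min[a, ]) * v) / sum(v * v)
      if (u < -1e-9 || u > 1 + 1e-9) next
      resid <- min(resid, sqrt(sum((x_min[a, ] + u * v - p)^2)))
    }
    expect_lt(resid, 1e-9)
  }
  # balanced input returned unchanged
  xb <- x[1:20, ]; yb <- rep(c("a", "b"), each = 10)
  same <- smote_oversample(xb, yb, seed = 5)
  expect_identical(same$x, xb)
  # minority of one is an error; tiny minority shrinks k with a warning
  expect_error(smote_oversample(x, rep(c("m", "M"), c(1, 59)), seed = 1),
               "minority")
  expect_warning(smote_oversample(x[1:13, ], rep(c("m", "M"), c(3, 10)),
                                  seed = 1), "k_neighbors")
})

test_that("greedy decollinearization enforces the correlation threshold", {
  set.seed(4)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  base <- rnorm(n) + y * 2
  x <- cbind(f1 = base, f2 = base,            # exact duplicate
             f3 = rnorm(n) + y, f4 = rnorm(n))
  sel <- select_noncollinear(x, y, threshold = 0.4)
  expect_true(sum(c("f1", "f2") %in% sel) == 1)
  # mutually orthogonal features are all retained
  xo <- diag(4)[rep(1:4, each = 3) + 0, ] + matrix(rnorm(48, sd = 1e-3), 12)
  colnames(xo) <- paste0("o", 1:4)
  expect_length(select_noncollinear(xo, rep(c(0, 1), 6), 0.4), 4)
  # brute-force pairwise check over random toys
  for (s in 1:5) {
    set.seed(s)
    xr <- matrix(rnorm(40 * 8), 40, 8,
                 dimnames = list(NULL, paste0("f", 1:8)))
    xr[, 2] <- xr[, 1] + rnorm(40, sd = 0.1)
    yr <- rep(c(0, 1), each = 20)
    selr <- select_noncollinear(xr, yr, threshold = 0.4)
    cc <- abs(cor(xr[, selr, drop = FALSE]))
    expect_true(all(cc[upper.tri(cc)] < 0.4))
  }
})

test_that("cross-validated scenarios are seeded, bounded and nested", {
  set.seed(6)
  n <- 60
  y <- factor(rep(c("ctrl", "case"), each = n / 2),
              levels = c("ctrl", "case"))
  x <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, paste0("g", 1:12)))
  x[y == "case", 1:4] <- x[y == "case", 1:4] + 1.5
  r1 <- run_scenario(x, y, "all_genes", n_folds = 5, seed = 9)
  r1b <- run_scenario(x, y, "all_genes", n_folds = 5, seed = 9)
  expect_identical(r1$per_fold, r1b$per_fold)
  expect_true(all(r1$per_fold >= 0 & r1$per_fold <= 1))
  expect_equal(nrow(r1$per_fold), 5)

  r3 <- run_scenario(x, y, "fold_stable_subset", n_folds = 5, seed = 9)
  for (feats in r3$features_per_fold)
    expect_true(all(r3$stable_features %in% feats))
  # the planted shift is detected
  expect_gt(r1$metrics$mean[r1$metrics$metric == "roc_auc"], 0.8)
})

test_that("random-gene baseline draws are seeded and respect exclusions", {
  set.seed(7)
  x <- matrix(rnorm(40 * 30), 40, 30,
              dimnames = list(NULL, paste0("g", 1:30)))
  y <- rep(c("a", "b"), each = 20)
  b1 <- random_gene_baseline(x, y, n_genes_per_draw = 5, n_classifiers = 3,
                             exclude = paste0("g", 1:10), seed = 21,
                             scenario = "all_genes", n_folds = 5)
  b2 <- random_gene_baseline(x, y, n_genes_per_draw = 5, n_classifiers = 3,
                             exclude = paste0("g", 1:10), seed = 21,
                             scenario = "all_genes", n_folds = 5)
  expect_identical(b1$draws, b2$draws)
  expect_identical(b1$per_classifier, b2$per_classifier)
  expect_false(any(unlist(b1$draws) %in% paste0("g", 1:10)))
  expect_error(random_gene_baseline(x, y, n_genes_per_draw = 25,
                                    exclude = paste0("g", 1:10), seed = 1),
               "not enough genes")
})
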