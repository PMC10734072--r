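test_that("theta = 0 reduces exactly to plain KL-NMF", {
  set.seed(4)
  V <- matrix(rgamma(30 * 12, 2, 0.5), 30, 12)
  W0 <- matrix(runif(30 * 3) * mean(V), 30, 3)
  H0 <- matrix(runif(3 * 12) * mean(V), 3, 12)
  fit <- nsnmf_factorize(V, 3, theta = 0, max_iter = 40, tol = 0,
                         init = list(W = W0, H = H0))
  ora <- kl_nmf_oracle(V, W0, H0, 40)
  expect_lt(max(abs(fit$W - ora$W)), 1e-10)
  expect_lt(max(abs(fit$H - ora$H)), 1e-10)
  expect_lt(max(abs(fit$loss_trace - ora$loss)), 1e-8)
})

test_that("an exactly factorizable rank-1 matrix is recovered", {
  set.seed(2)
  V <- outer(rgamma(25, 3), rgamma(8, 3))
  fit <- nsnmf_factorize(V, 1, theta = 0.5, max_iter = 5000, tol = 0,
                         seed = 1)
  expect_lt(tail(fit$loss_trace, 1), 1e-6)
})

test_that("KL loss is monotone non-increasing and factors stay non-negative", {
  set.seed(12)
  for (rep in 1:5) {
    V <- matrix(rgamma(30 * 12, 2, 0.5), 30, 12)
    fit <- nsnmf_factorize(V, 3, theta = runif(1), max_iter = 150,
                           tol = 0, seed = rep)
    expect_true(all(diff(fit$loss_trace) <= 1e-8 *
                      pmax(abs(head(fit$loss_trace, -1)), 1)))
    expect_true(all(fit$W >= 0))
    expect_true(all(fit$H >= 0))
  }
})

test_that("invalid input is rejected", {
  V <- matrix(1, 4, 3)
  expect_error(nsnmf_factorize(cbind(V, 0), 2, seed = 1), "all-zero")
  Vn <- V; Vn[1] <- -1
  expect_error(nsnmf_factorize(Vn, 2, seed = 1), "non-negative")
  Vna <- V; Vna[1] <- NA
  expect_error(nsnmf_factorize(Vna, 2, seed = 1), "NA")
  expect_error(nsnmf_factorize(V, 2, theta = 1.5, seed = 1), "theta")
})

test_that("returned basis columns are normalized with compensating H", {
  set.seed(3)
  V <- matrix(rgamma(40 * 10, 2, 1), 40, 10)
  fit <- nsnmf_factorize(V, 3, theta = 0.4, max_iter = 100, seed = 2)
  expect_equal(unname(colSums(fit$W)), rep(1, 3), tolerance = 1e-12)
})

test_that("sample assignment takes the argmax with lowest-index ties", {
  fake <- list(H = cbind(c(0.9, 0.05, 0.05), c(0.4, 0.4, 0.2),
                         c(0.1, 0.2, 0.7)), k = 3L)
  expect_equal(unname(assign_samples(fake)), c(1L, 1L, 3L))
  fake$H[, 2] <- 0
  expect_error(assign_samples(fake), "all-zero")
})

test_that("gene posteriors and feature scores behave at the entropy limits", {
  W <- rbind(onehot = c(5, 0, 0), uniform = c(1, 1, 1), zero = c(0, 0, 0),
             mid = c(3, 1, 0))
  H <- matrix(runif(3 * 4) + 0.1, 3, 4)
  fake <- structure(list(W = W, H = H, k = 3L), class = "nsnmf_fit")
  cm <- extract_informative_genes(fake)
  expect_equal(unname(cm$gene_posteriors["onehot", ]), c(1, 0, 0))
  expect_equal(unname(cm$feature_scores[["onehot"]]), 1)
  expect_equal(unname(cm$feature_scores[["uniform"]]), 0, tolerance = 1e-12)
  expect_identical(cm$flagged_genes, "zero")
  expect_true(all(is.na(cm$gene_posteriors["zero", ])))
  rs <- rowSums(cm$gene_posteriors[c("onehot", "uniform", "mid"), ])
  expect_equal(unname(rs), rep(1, 3), tolerance = 1e-9)
})

test_that("informative gene sets are pairwise disjoint on real fits", {
  fx <- fixture_discovery()
  genes <- unlist(fx$model$informative_genes)
  expect_equal(anyDuplicated(genes), 0)
})

test_that("planted clusters are recovered at moderate scale", {
  cfg <- small_config(seed = 17)
  d <- generate_discovery(cfg)
  prep <- preprocess(d, n_top = 200)
  fit <- nsnmf_factorize(prep$matrix$values, 3, seed = 5)
  expect_gte(ari(assign_samples(fit), d$truth$labels), 0.9)
})

test_that("consensus matrices satisfy their structural invariants", {
  cfg <- small_config(seed = 23, n_genes = 120, n_samples = 24,
                      signature_size = 15)
  d <- generate_discovery(cfg)
  prep <- preprocess(d, n_top = 80)
  V <- prep$matrix$values
  cc <- consensus_cluster(V, k_range = 2:3, n_runs = 4, max_iter = 150,
                          seed = 9)
  for (pk in cc$per_k) {
    C <- pk$consensus
    expect_equal(C, t(C))
    expect_equal(unname(diag(C)), rep(1, ncol(V)))
    expect_true(all(C >= 0 & C <= 1))
    expect_true(pk$cophenetic >= -1 && pk$cophenetic <= 1)
  }
  # single run gives a binary connectivity matrix
  c1 <- consensus_cluster(V, k_range = 2, n_runs = 1, max_iter = 100,
                          seed = 9)
  expect_true(all(c1$per_k$k2$consensus %in% c(0, 1)))
  # bit-identical reproduction from the master seed
  cc2 <- consensus_cluster(V, k_range = 2:3, n_runs = 4, max_iter = 150,
                           seed = 9)
  expect_identical(cc$per_k$k3$consensus, cc2$per_k$k3$consensus)
  expect_identical(cc$chosen_k, cc2$chosen_k)
})

test_that("converged consensus is equivariant to sample permutation", {
  cfg <- small_config(seed = 29, n_genes = 150, n_samples = 24,
                      signature_size = 20, log2_fold_change = 4)
  d <- generate_discovery(cfg)
  V <- preprocess(d, n_top = 100)$matrix$values
  cc <- consensus_cluster(V, k_range = 3, n_runs = 6, max_iter = 800,
                          tol = 1e-7, seed = 2)$per_k$k3$consensus
  set.seed(1)
  perm <- sample(ncol(V))
  ccp <- consensus_cluster(V[, perm], k_range = 3, n_runs = 6,
                           max_iter = 800, tol = 1e-7,
                           seed = 2)$per_k$k3$consensus
  # on cleanly separated data the consensus is the 0/1 co-membership
  # matrix, which must commute with any relabeling of the samples
  expect_equal(ccp, cc[perm, perm])
})

test_that("smoothing increases the Hoyer sparseness of the basis", {
  set.seed(10)
  V <- matrix(rgamma(60 * 24, 2, 0.5), 60, 24)
  W0 <- matrix(runif(60 * 3) * mean(V), 60, 3)
  H0 <- matrix(runif(3 * 24) * mean(V), 3, 24)
  sp <- vapply(c(0, 0.5, 0.9), function(th)
    mean(apply(nsnmf_factorize(V, 3, theta = th, max_iter = 800,
                               tol = 1e-7,
                               init = list(W = W0, H = H0))$W, 2,
               hoyer_sparseness)), numeric(1))
  expect_false(is.unsorted(sp))
  expect_equal(hoyer_sparseness(c(1, 0, 0, 0)), 1)
  expect_equal(hoyer_sparseness(rep(2, 4)), 0, tolerance = 1e-12)
})
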