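# Shared fixtures and independent oracles used across the test files.

# Small synthetic configuration for fast tests.
small_config <- function(seed = 7, ...) {
  args <- list(n_genes = 400, n_samples = 60, k_clusters = 3,
               signature_size = 20, log2_fold_change = 2,
               nb_dispersion = 0.2, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

# Independent plain KL-NMF oracle (Lee-Seung multiplicative updates with
# the same epsilon flooring as the package engine), used to check the
# theta = 0 degeneration of nsNMF.
kl_nmf_oracle <- function(V, W, H, iters, eps = 1e-12) {
  loss <- numeric(iters)
  idx <- V > 0
  vlogv <- sum(V[idx] * log(V[idx]))
  sumV <- sum(V)
  for (it in seq_len(iters)) {
    H <- H * crossprod(W, V / pmax(W %*% H, eps)) / pmax(colSums(W), eps)
    W <- W * ((V / pmax(W %*% H, eps)) %*% t(H))
    W <- sweep(W, 2, pmax(rowSums(H), eps), "/")
    P <- W %*% H
    loss[it] <- vlogv - sum(V[idx] * log(pmax(P[idx], eps))) + sum(P) - sumV
  }
  cs <- colSums(W)
  list(W = sweep(W, 2, cs, "/"), H = H * cs, loss = loss)
}

# Adjusted Rand index between two partitions (closed form from the
# pair-counting contingency table).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Map package cluster indices to planted truth labels by maximum overlap,
# then score agreement.
mapped_accuracy <- function(assigned, truth_fit_labels, truth_target_labels,
                            fit_labels) {
  map <- table(fit_labels, truth_fit_labels)
  perm <- apply(map, 1, which.max)
  mean(perm[as.integer(assigned)] == truth_target_labels)
}

# Discovery + fitted cluster model used by several transfer/validation
# tests (computed once per test file load).
fixture_discovery <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(seed = 7)
      d <- generate_discovery(cfg)
      prep <- preprocess(d, n_top = 500)
      fit <- nsnmf_factorize(prep$matrix$values, 3, seed = 1)
      cache <<- list(cfg = cfg, data = d, prep = prep, fit = fit,
                     model = extract_informative_genes(fit))
    }
    cache
  }
})
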