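#' Fit a non-smooth NMF factorization
#'
#' Factorizes a non-negative genes x samples matrix as `V ~ W S H`, where
#' `S = (1 - theta) I + (theta / k) 11'` is the non-smooth NMF smoothing
#' matrix. `theta = 0` reduces exactly to standard KL-divergence NMF; larger
#' `theta` forces the smoothing into the reconstruction and drives `W` and
#' `H` towards sparser solutions. Updates are multiplicative KL
#' (Lee-Seung form with the effective basis `W S` for the `H` step and the
#' effective coefficients `S H` for the `W` step), with ratios floored at
#' `eps` to avoid 0/0. Iteration stops at `max_iter` or when the relative
#' change in KL divergence drops below `tol`. At convergence the columns of
#' `W` are normalized to unit sum with a compensating rescale of `H`
#' (applied once at the end, so the recorded loss trace is exactly the
#' monotone trace of the raw multiplicative updates).
#'
#' @param V non-negative numeric matrix (genes x samples), no all-zero
#'   columns, no NA/NaN.
#' @param k factorization rank (>= 1).
#' @param theta smoothing parameter in \[0, 1\] (default 0.5).
#' @param max_iter maximum iterations (default 1000).
#' @param tol relative KL-change convergence tolerance (default 1e-5).
#' @param seed optional integer seed for the random initialization.
#' @param init optional list with `W` (genes x k) and `H` (k x samples)
#'   non-negative starting matrices; overrides the random init.
#' @param eps flooring constant inside multiplicative ratios (default 1e-12).
#' @return object of class `nsnmf_fit`: `W`, `H`, `k`, `theta`,
#'   `loss_trace` (KL divergence per iteration), `converged`, `iterations`.
#' @export
nsnmf_factorize <- function(V, k, theta = 0.5, max_iter = 1000, tol = 1e-5,
                            seed = NULL, init = NULL, eps = 1e-12) {
  V <- as.matrix(V)
  if (anyNA(V) || any(!is.finite(V))) stop("V contains NA/NaN/Inf")
  if (any(V < 0)) stop("V must be non-negative")
  if (any(colSums(V) == 0)) stop("V has all-zero columns")
  if (k < 1 || k != round(k)) stop("k must be a positive integer")
  if (theta < 0 || theta > 1) stop("theta must be in [0, 1]")
  if (is.null(init)) {
    if (!is.null(seed)) set.seed(seed)
    mv <- mean(V)
    init <- list(W = matrix(stats::runif(nrow(V) * k) * mv, nrow(V), k),
                 H = matrix(stats::runif(k * ncol(V)) * mv, k, ncol(V)))
  }
  stopifnot(nrow(init$W) == nrow(V), ncol(init$W) == k,
            nrow(init$H) == k, ncol(init$H) == ncol(V))
  res <- nsnmf_engine(V, init$W, init$H, theta, as.integer(max_iter),
                      tol, eps)
  W <- res$W
  H <- res$H
  cs <- colSums(W)
  pos <- cs > 0
  W[, pos] <- sweep(W[, pos, drop = FALSE], 2, cs[pos], `/`)
  H[pos, ] <- H[pos, , drop = FALSE] * cs[pos]
  rownames(W) <- rownames(V)
  colnames(H) <- colnames(V)
  structure(list(W = W, H = H, k = as.integer(k), theta = theta,
                 loss_trace = res$loss_trace, converged = res$converged,
                 iterations = length(res$loss_trace)),
            class = "nsnmf_fit")
}

#' @export
print.nsnmf_fit <- function(x, ...) {
  cat(sprintf("nsnmf_fit: k=%d, theta=%.2f, %d iterations (%s), KL=%.4g\n",
              x$k, x$theta, x$iterations,
              if (x$converged) "converged" else "max_iter",
              utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' Assign samples to clusters from a factorization
#'
#' Each sample is assigned to the basis component with the largest
#' coefficient in its column of `H`; ties go to the lowest index.
#'
#' @param fit an `nsnmf_fit`.
#' @return integer vector of cluster labels in `1..k`, named by sample.
#' @export
assign_samples <- function(fit) {
  H <- fit$H
  if (any(colSums(H) == 0)) stop("H has all-zero columns; cannot assign")
  labels <- apply(H, 2, which.max)   # which.max takes the first (lowest) max
  stats::setNames(as.integer(labels), colnames(H))
}

#' Extract informative genes and gene posteriors
#'
#' Row-normalizes the basis matrix into gene posterior probabilities
#' `p[g, j] = W[g, j] / sum_j W[g, j]` and computes the entropy-based
#' feature score `f_g = 1 + (1 / log2 k) * sum_j p[g, j] log2 p[g, j]`
#' (0 for a uniform row, 1 for a one-hot row; `0 log 0 := 0`). Genes with
#' `f_g > median(f) + cutoff_mads * MAD(f)` (plain MAD, no consistency
#' constant) are called informative and uniquely assigned to the cluster
#' with the largest basis weight, yielding pairwise disjoint signatures.
#' All-zero rows of `W` are flagged and excluded, never normalized.
#'
#' @param fit an `nsnmf_fit` with `k >= 2`.
#' @param cutoff_mads robust cutoff multiplier (default 3).
#' @return object of class `cluster_model`: `sample_labels`,
#'   `gene_posteriors` (row-stochastic genes x k), `informative_genes`
#'   (list of k disjoint gene-ID vectors), `feature_scores`,
#'   `flagged_genes` (all-zero rows), `threshold`.
#' @export
extract_informative_genes <- function(fit, cutoff_mads = 3) {
  if (fit$k < 2) stop("informative-gene extraction requires k >= 2")
  W <- fit$W
  ids <- rownames(W)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(W)))
  rs <- rowSums(W)
  flagged <- ids[rs == 0]
  ok <- rs > 0
  P <- W[ok, , drop = FALSE] / rs[ok]
  plogp <- P * log2(P)
  plogp[P == 0] <- 0
  f <- 1 + rowSums(plogp) / log2(fit$k)
  med <- stats::median(f)
  madf <- stats::median(abs(f - med))
  thr <- med + cutoff_mads * madf
  informative <- f > thr
  memb <- max.col(W[ok, , drop = FALSE], ties.method = "first")
  sets <- lapply(seq_len(fit$k), function(j)
    ids[ok][informative & memb == j])
  names(sets) <- paste0("cluster", seq_len(fit$k))
  post <- matrix(NA_real_, nrow(W), fit$k,
                 dimnames = list(ids, paste0("cluster", seq_len(fit$k))))
  post[ok, ] <- P
  structure(list(sample_labels = assign_samples(fit),
                 gene_posteriors = post,
                 informative_genes = sets,
                 feature_scores = stats::setNames(f, ids[ok]),
                 flagged_genes = flagged, threshold = thr),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: %d clusters, informative genes: %s\n",
              length(x$informative_genes),
              paste(lengths(x$informative_genes), collapse = "/")))
  invisible(x)
}

#' Consensus clustering with cophenetic rank selection
#'
#' For each rank `k` in `k_range`, runs `n_runs` independently seeded
#' factorizations, records the sample connectivity matrix of each run
#' (1 when two samples share the argmax basis component), and averages
#' them into a consensus matrix. The cophenetic correlation between the
#' consensus dissimilarity `1 - C` and the cophenetic distances of its
#' average-linkage dendrogram measures partition stability; the chosen rank
#' maximizes it (ties go to the smallest k). Runs that leave a cluster
#' empty are kept and counted.
#'
#' @param V non-negative genes x samples matrix.
#' @param k_range integer vector of ranks to scan (each >= 2 and
#'   <= samples - 1).
#' @param n_runs factorizations per rank (default 100).
#' @param theta,max_iter,tol,eps passed to [nsnmf_factorize()].
#' @param seed master seed; per-run seeds are derived deterministically.
#' @return object of class `consensus_result`: per-k list with `consensus`,
#'   `cophenetic`, `silhouette` (mean silhouette of the consensus
#'   partition), `degenerate_runs`; plus `chosen_k`, `k_range`, `summary`
#'   data.frame.
#' @export
consensus_cluster <- function(V, k_range = 2:10, n_runs = 100, theta = 0.5,
                              max_iter = 1000, tol = 1e-5, seed = 1L,
                              eps = 1e-12) {
  V <- as.matrix(V)
  n <- ncol(V)
  if (any(k_range < 2) || any(k_range > n - 1))
    stop("each k must be >= 2 and <= samples - 1")
  set.seed(seed)
  run_seeds <- matrix(sample.int(.Machine$integer.max - 1,
                                 n_runs * length(k_range)),
                      nrow = n_runs)
  per_k <- vector("list", length(k_range))
  names(per_k) <- paste0("k", k_range)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    consensus <- matrix(0, n, n)
    degenerate <- 0L
    for (r in seq_len(n_runs)) {
      fit <- nsnmf_factorize(V, k, theta = theta, max_iter = max_iter,
                             tol = tol, seed = run_seeds[r, i], eps = eps)
      lab <- assign_samples(fit)
      if (length(unique(lab)) < k) degenerate <- degenerate + 1L
      consensus <- consensus + outer(lab, lab, `==`)
    }
    consensus <- consensus / n_runs
    dimnames(consensus) <- list(colnames(V), colnames(V))
    d <- stats::as.dist(1 - consensus)
    hc <- stats::hclust(d, method = "average")
    coph <- stats::cor(d, stats::cophenetic(hc))
    part <- stats::cutree(hc, k = k)
    sil <- if (length(unique(part)) > 1)
      mean(cluster::silhouette(part, d)[, "sil_width"]) else NA_real_
    per_k[[i]] <- list(consensus = consensus, cophenetic = coph,
                       silhouette = sil, partition = part,
                       degenerate_runs = degenerate)
  }
  coph_all <- vapply(per_k, `[[`, numeric(1), "cophenetic")
  chosen_k <- k_range[which.max(coph_all)]   # first max = smallest k on ties
  structure(list(per_k = per_k, k_range = k_range, chosen_k = chosen_k,
                 summary = data.frame(
                   k = k_range, cophenetic = unname(coph_all),
                   silhouette = vapply(per_k, `[[`, numeric(1), "silhouette"),
                   degenerate_runs = vapply(per_k, `[[`, integer(1),
                                            "degenerate_runs"))),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result: chosen k =", x$chosen_k, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Hoyer sparseness of a non-negative vector
#'
#' `(sqrt(n) - ||x||_1 / ||x||_2) / (sqrt(n) - 1)`: 0 for a flat vector,
#' 1 for a one-hot vector. Used to characterize how the smoothing
#' parameter `theta` sparsifies the basis.
#'
#' @param x numeric vector.
#' @return sparseness in \[0, 1\].
#' @export
hoyer_sparseness <- function(x) {
  n <- length(x)
  if (n < 2 || all(x == 0)) return(NA_real_)
  (sqrt(n) - sum(abs(x)) / sqrt(sum(x^2))) / (sqrt(n) - 1)
}
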