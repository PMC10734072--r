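#' Intersect signature genes with a target dataset
#'
#' Returns the signature genes present in the target, in discovery
#' signature order (deterministic), and logs per-cluster intersection
#' counts as an attribute.
#'
#' @param signatures list of per-cluster gene-ID vectors (or a single
#'   character vector).
#' @param target an [expression_dataset()], `normalized_matrix`, or a
#'   character vector of target gene IDs.
#' @return character vector of shared genes with attribute
#'   `per_cluster_counts`.
#' @export
intersect_genes <- function(signatures, target) {
  target_ids <- if (inherits(target, "expression_dataset")) target$gene_ids
    else if (inherits(target, "normalized_matrix")) rownames(target$values)
    else if (is.matrix(target)) rownames(target)
    else as.character(target)
  sigs <- if (is.list(signatures)) signatures else list(signatures)
  shared_per <- lapply(sigs, function(s) s[s %in% target_ids])
  shared <- unlist(shared_per, use.names = FALSE)
  shared <- shared[!duplicated(shared)]
  if (length(shared) == 0)
    stop("no signature genes are present in the target dataset")
  attr(shared, "per_cluster_counts") <- lengths(shared_per)
  shared
}

#' Fit a regularized linear discriminant model
#'
#' Gaussian LDA with a shared within-class covariance: per-class means,
#' pooled within-class covariance with a ridge penalty
#' `lambda * mean(diag(Sigma)) * I` (required because the number of
#' signature genes can exceed the number of samples), and class-frequency
#' priors. A discriminant basis projecting to at most k-1 dimensions is
#' derived from the whitened between-class scatter and is used as the
#' feature space for silhouette computations.
#'
#' @param x genes x samples matrix restricted to the shared genes (or a
#'   `normalized_matrix`).
#' @param labels per-sample class labels (>= 2 classes, each with >= 2
#'   samples).
#' @param lambda ridge multiplier on the mean within-class variance
#'   (default 1e-3).
#' @return object of class `lda_model`: `shared_genes`, `class_means`
#'   (k x p), `pooled_covariance` (regularized, positive definite),
#'   `priors`, `scaling` (p x (k-1) discriminant basis), `classes`.
#' @export
fit_lda <- function(x, labels, lambda = 1e-3) {
  m <- if (inherits(x, "normalized_matrix")) x$values else as.matrix(x)
  xt <- t(m)                               # samples x features
  labels <- as.factor(labels)
  counts <- table(labels)
  if (length(counts) < 2) stop("need at least 2 classes")
  if (any(counts < 2)) stop("every class needs at least 2 samples: ",
                            paste(names(counts)[counts < 2], collapse = ", "))
  classes <- names(counts)
  k <- length(classes)
  p <- ncol(xt)
  n <- nrow(xt)
  means <- t(vapply(classes, function(cl)
    colMeans(xt[labels == cl, , drop = FALSE]), numeric(p)))
  if (p == 1) means <- t(means)   # vapply collapses p = 1 to a vector
  centered <- xt - means[as.integer(labels), , drop = FALSE]
  Sw <- crossprod(centered) / (n - k)
  Sw <- Sw + lambda * mean(diag(Sw)) * diag(p)
  priors <- as.numeric(counts) / n
  # whiten, then eigen-decompose the between-class scatter
  R <- chol(Sw)
  gmean <- colSums(means * priors)
  Mw <- t(backsolve(R, t(means) - gmean, transpose = TRUE)) *
    sqrt(priors)                            # k x p whitened weighted means
  sv <- svd(Mw, nu = 0, nv = min(k - 1, p))
  scaling <- backsolve(R, sv$v)
  rownames(scaling) <- rownames(m)
  structure(list(shared_genes = rownames(m), class_means = means,
                 pooled_covariance = Sw, priors = stats::setNames(priors,
                                                                  classes),
                 scaling = scaling, classes = classes, lambda = lambda),
            class = "lda_model")
}

#' Assign target samples to discovery clusters
#'
#' Computes the Gaussian discriminant score of every sample for each class
#' (`x' Sigma^-1 mu_c - mu_c' Sigma^-1 mu_c / 2 + log prior_c`) and converts
#' the scores to posterior probabilities by softmax. The hard label is the
#' argmax posterior. The k x k `avg_posterior` summary averages the
#' posterior vectors within each assigned cluster (rows = assigned cluster).
#'
#' @param model an `lda_model`.
#' @param target genes x samples matrix (or `normalized_matrix` /
#'   [expression_dataset()]) containing every shared gene; extra genes are
#'   ignored, missing genes are an error.
#' @return object of class `assignment_result`: `labels`, `posteriors`
#'   (samples x k, rows sum to 1), `avg_posterior` (k x k).
#' @export
assign_clusters <- function(model, target) {
  m <- if (inherits(target, "expression_dataset")) target$values
    else if (inherits(target, "normalized_matrix")) target$values
    else as.matrix(target)
  missing <- setdiff(model$shared_genes, rownames(m))
  if (length(missing))
    stop("target is missing shared genes: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)",
                                          length(missing) - 5) else "")
  xt <- t(m[model$shared_genes, , drop = FALSE])
  Sinv_mu <- solve(model$pooled_covariance, t(model$class_means))
  scores <- xt %*% Sinv_mu
  const <- -0.5 * colSums(t(model$class_means) * Sinv_mu) +
    log(model$priors)
  scores <- sweep(scores, 2, const, `+`)
  post <- exp(scores - apply(scores, 1, max))
  post <- post / rowSums(post)
  colnames(post) <- model$classes
  labels <- model$classes[max.col(post, ties.method = "first")]
  k <- length(model$classes)
  avg <- matrix(NA_real_, k, k, dimnames = list(assigned = model$classes,
                                                cluster = model$classes))
  for (cl in model$classes) {
    rows <- labels == cl
    if (any(rows)) avg[cl, ] <- colMeans(post[rows, , drop = FALSE])
  }
  structure(list(labels = stats::setNames(labels, rownames(xt)),
                 posteriors = post, avg_posterior = avg),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("assignment_result:", length(x$labels), "samples\n")
  print(table(x$labels))
  cat("average posterior by assigned cluster:\n")
  print(round(x$avg_posterior, 3))
  invisible(x)
}

# Project samples into the discriminant space of a model.
discriminant_space <- function(model, m) {
  t(m[model$shared_genes, , drop = FALSE]) %*% model$scaling
}

#' Bootstrap stability of a transferred cluster assignment
#'
#' With the one-shot assignment of the target fixed as reference labels,
#' each iteration resamples the target samples with replacement, refits the
#' LDA on the resample (using the reference labels), reassigns *all*
#' original samples with the refit model, and records (i) the fraction
#' agreeing with the reference (accuracy) and (ii) the mean silhouette of
#' the reference labels in the refit discriminant space (Euclidean).
#' Resamples missing a class (or leaving one with a single sample) are
#' redrawn and counted. Reported are the medians and percentile 95% CIs.
#'
#' @param model an `lda_model` fitted on the discovery data.
#' @param target genes x samples matrix containing all shared genes.
#' @param n_iterations bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @return object of class `bootstrap_stability`: `n_iterations`,
#'   `median_accuracy`, `accuracy_ci`, `median_silhouette`,
#'   `silhouette_ci`, `redraws`, per-iteration vectors.
#' @export
bootstrap_stability <- function(model, target, n_iterations = 1000,
                                seed = 1L) {
  m <- if (inherits(target, "normalized_matrix")) target$values
    else if (inherits(target, "expression_dataset")) target$values
    else as.matrix(target)
  m <- m[model$shared_genes, , drop = FALSE]
  ref <- assign_clusters(model, m)$labels
  n <- ncol(m)
  set.seed(seed)
  acc <- sil <- numeric(n_iterations)
  redraws <- 0L
  ref_f <- factor(ref, levels = model$classes)
  for (i in seq_len(n_iterations)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      tab <- table(factor(ref[idx], levels = model$classes))
      if (all(tab >= 2)) break
      redraws <- redraws + 1L
    }
    refit <- fit_lda(m[, idx, drop = FALSE], ref[idx], lambda = model$lambda)
    acc[i] <- mean(assign_clusters(refit, m)$labels == ref)
    proj <- discriminant_space(refit, m)
    sil[i] <- mean(cluster::silhouette(as.integer(ref_f),
                                       stats::dist(proj))[, "sil_width"])
  }
  structure(list(n_iterations = n_iterations,
                 median_accuracy = stats::median(acc),
                 accuracy_ci = stats::quantile(acc, c(0.025, 0.975),
                                               names = FALSE),
                 median_silhouette = stats::median(sil),
                 silhouette_ci = stats::quantile(sil, c(0.025, 0.975),
                                                 names = FALSE),
                 accuracy = acc, silhouette = sil, redraws = redraws),
            class = "bootstrap_stability")
}

#' @export
print.bootstrap_stability <- function(x, ...) {
  cat(sprintf("bootstrap_stability (%d iterations):\n", x$n_iterations))
  cat(sprintf("  median accuracy   %.3f (95%% CI %.3f-%.3f)\n",
              x$median_accuracy, x$accuracy_ci[1], x$accuracy_ci[2]))
  cat(sprintf("  median silhouette %.3f (95%% CI %.3f-%.3f)\n",
              x$median_silhouette, x$silhouette_ci[1], x$silhouette_ci[2]))
  invisible(x)
}

# Maximum-overlap mapping between two labelings via exhaustive permutation
# search on the contingency table (k is small in this setting). Returns the
# permutation perm such that de-novo cluster j maps to reference cluster
# perm[j], maximizing the total matched count.
best_cluster_mapping <- function(denovo, reference) {
  tab <- table(denovo, reference)
  r <- nrow(tab); c <- ncol(tab)
  k <- max(r, c)
  padded <- matrix(0, k, k)
  padded[seq_len(r), seq_len(c)] <- tab
  perms <- all_permutations(k)
  scores <- vapply(perms, function(p)
    sum(padded[cbind(seq_len(k), p)]), numeric(1))
  best <- perms[[which.max(scores)]]
  list(perm = best[seq_len(r)], table = tab)
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1))
    for (pos in 0:(k - 1))
      out[[length(out) + 1L]] <- append(p, k, after = pos)
  out
}

#' Reverse validation by de-novo re-clustering of the target
#'
#' Clusters the target dataset from scratch (preprocessing, variable-gene
#' selection, nsNMF at the reference number of clusters, best of `n_runs`
#' by final KL loss) and compares the de-novo labels with the transferred
#' reference labels: de-novo clusters are matched to reference clusters by
#' maximum overlap (optimal assignment on the contingency table), and the
#' per-reference-cluster agreement fractions are reported. A k mismatch is
#' handled by the best rectangular mapping and logged.
#'
#' @param target an [expression_dataset()] (counts or normalized).
#' @param reference_labels per-sample reference cluster labels (same sample
#'   order as `target`).
#' @param k number of de-novo clusters (default: number of distinct
#'   reference labels).
#' @param n_top variable genes for the de-novo clustering (default 5000).
#' @param n_runs,theta,max_iter,tol,seed nsNMF settings; the best of
#'   `n_runs` seeded runs (lowest final KL) is used.
#' @param filter apply the gene filter during preprocessing.
#' @return list with `overlap` (named per-reference-cluster agreement
#'   fractions), `mapping`, `contingency`, `denovo_labels`.
#' @export
reverse_validate <- function(target, reference_labels, k = NULL,
                             n_top = 5000, n_runs = 20, theta = 0.5,
                             max_iter = 500, tol = 1e-5, seed = 1L,
                             filter = FALSE) {
  stopifnot(length(reference_labels) == ncol(target$values))
  ref <- as.integer(factor(reference_labels))
  if (is.null(k)) k <- length(unique(ref))
  prep <- preprocess(target, n_top = n_top, filter = filter)
  V <- prep$matrix$values
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1, n_runs)
  best <- NULL
  for (s in run_seeds) {
    fit <- nsnmf_factorize(V, k, theta = theta, max_iter = max_iter,
                           tol = tol, seed = s)
    if (is.null(best) ||
        utils::tail(fit$loss_trace, 1) < utils::tail(best$loss_trace, 1))
      best <- fit
  }
  denovo <- assign_samples(best)
  map <- best_cluster_mapping(denovo, ref)
  k_ref <- length(unique(ref))
  overlap <- numeric(k_ref)
  for (j in seq_len(k_ref)) {
    in_ref <- ref == j
    matched <- which(map$perm == j)
    overlap[j] <- if (length(matched))
      sum(denovo[in_ref] %in% matched) / sum(in_ref) else 0
  }
  names(overlap) <- paste0("cluster", seq_len(k_ref))
  list(overlap = overlap, mapping = map$perm, contingency = map$table,
       denovo_labels = denovo)
}
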