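#' Stratified k-fold partition
#'
#' Shuffles the samples within each class and deals them round-robin into
#' `n_folds` folds, so per-fold class proportions stay within one sample of
#' the global proportions and the folds partition the data.
#'
#' @param labels per-sample class labels; every class must have at least
#'   `n_folds` members.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for the within-class shuffle.
#' @return list of `n_folds` integer index vectors (the held-out sets).
#' @export
stratified_folds <- function(labels, n_folds = 10, seed = 1L) {
  labels <- as.factor(labels)
  if (n_folds < 2) stop("n_folds must be >= 2")
  counts <- table(labels)
  if (any(counts < n_folds))
    stop("class smaller than n_folds: ",
         paste(names(counts)[counts < n_folds], collapse = ", "))
  set.seed(seed)
  folds <- vector("list", n_folds)
  offset <- 0L
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold_of <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
    for (f in seq_len(n_folds))
      folds[[f]] <- c(folds[[f]], idx[fold_of == f])
    offset <- (offset + length(idx)) %% n_folds
  }
  folds
}

#' SMOTE oversampling of the minority class
#'
#' Balances a binary training set by interpolating synthetic minority
#' points: `x_new = x_i + u (x_nn - x_i)` with `u ~ Uniform(0, 1)` and
#' `x_nn` one of the `k_neighbors` nearest minority neighbours of `x_i`
#' (Euclidean). Already balanced input is returned unchanged.
#'
#' @param x samples x features numeric matrix.
#' @param y binary labels (factor or coercible).
#' @param k_neighbors number of neighbours (default 5; reduced with a
#'   warning when the minority class is too small).
#' @param seed integer seed.
#' @return list with balanced `x` and `y` (original rows first).
#' @export
smote_oversample <- function(x, y, k_neighbors = 5, seed = 1L) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("SMOTE here is binary-only")
  counts <- table(y)
  if (counts[1] == counts[2]) return(list(x = x, y = y))
  minority <- names(counts)[which.min(counts)]
  n_min <- min(counts)
  if (n_min < 2) stop("minority class of 1 sample cannot be oversampled")
  if (n_min <= k_neighbors) {
    warning("k_neighbors reduced to ", n_min - 1)
    k_neighbors <- n_min - 1
  }
  set.seed(seed)
  xm <- x[y == minority, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  n_new <- max(counts) - n_min
  base_idx <- sample(rep_len(seq_len(n_min), n_new))
  synth <- matrix(NA_real_, n_new, ncol(x))
  for (i in seq_len(n_new)) {
    b <- base_idx[i]
    nn <- order(d[b, ])[seq_len(k_neighbors)]
    j <- nn[sample.int(k_neighbors, 1)]
    u <- stats::runif(1)
    synth[i, ] <- xm[b, ] + u * (xm[j, ] - xm[b, ])
  }
  colnames(synth) <- colnames(x)
  list(x = rbind(x, synth),
       y = factor(c(as.character(y), rep(minority, n_new)),
                  levels = levels(y)))
}

# One-way ANOVA F statistic of each feature against the class labels
# (the univariate scorer used to rank features before decollinearization).
anova_f_scores <- function(x, y) {
  y <- as.factor(y)
  n <- nrow(x)
  k <- nlevels(y)
  gm <- colMeans(x)
  ssb <- ssw <- numeric(ncol(x))
  for (cl in levels(y)) {
    xi <- x[y == cl, , drop = FALSE]
    mi <- colMeans(xi)
    ssb <- ssb + nrow(xi) * (mi - gm)^2
    ssw <- ssw + colSums(sweep(xi, 2, mi)^2)
  }
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[!is.finite(f)] <- -Inf   # constant features rank last
  f
}

#' Greedy decollinearized feature selection
#'
#' Ranks features by their one-way ANOVA F value against the labels
#' (descending) and accepts a feature only if its absolute Pearson
#' correlation with every already-accepted feature is below `threshold`.
#' At worst the single top-F feature is returned.
#'
#' @param x samples x features matrix (column names used as feature IDs).
#' @param y class labels.
#' @param threshold correlation threshold in (0, 1) (default 0.4).
#' @return character vector (or integer indices when unnamed) of accepted
#'   features in acceptance order.
#' @export
select_noncollinear <- function(x, y, threshold = 0.4) {
  x <- as.matrix(x)
  if (ncol(x) < 2) return(colnames(x) %||% seq_len(ncol(x)))
  f <- anova_f_scores(x, y)
  ord <- order(-f)
  accepted <- ord[1]
  for (j in ord[-1]) {
    r <- suppressWarnings(
      abs(stats::cor(x[, j], x[, accepted, drop = FALSE])))
    r[is.na(r)] <- 0     # constant feature: no linear dependence
    if (all(r < threshold)) accepted <- c(accepted, j)
  }
  colnames(x)[accepted] %||% accepted
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rank-based ROC AUC (Mann-Whitney); `scores` for the positive class.
roc_auc <- function(scores, y_positive) {
  n1 <- sum(y_positive)
  n0 <- sum(!y_positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Ridge (L2) logistic regression with the regularization strength chosen by
# inner stratified CV on ROC AUC. Returns a predict(newx) closure.
fit_l2_logistic <- function(x, y, lambda_grid = 10^seq(-4, 1, length.out = 8),
                            inner_folds = 3, seed = 1L) {
  y <- as.factor(y)
  pos <- levels(y)[2]
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  if (ncol(x) == 1) {      # glmnet needs >= 2 columns; plain GLM suffices
    df <- data.frame(y = y, x1 = x[, 1])
    fit <- stats::glm(y ~ x1, data = df, family = stats::binomial())
    return(function(newx)
      stats::predict(fit, data.frame(x1 = newx[, 1]), type = "response"))
  }
  folds <- stratified_folds(y, n_folds = inner_folds, seed = seed)
  auc <- matrix(NA_real_, inner_folds, length(lambda_grid))
  for (f in seq_len(inner_folds)) {
    te <- folds[[f]]
    fit <- glmnet::glmnet(x[-te, , drop = FALSE], y[-te],
                          family = "binomial", alpha = 0,
                          lambda = lambda_grid, standardize = FALSE)
    pred <- stats::predict(fit, x[te, , drop = FALSE], type = "response")
    for (l in seq_len(ncol(pred)))
      auc[f, l] <- roc_auc(pred[, l], y[te] == pos)
  }
  best <- which.max(colMeans(auc, na.rm = TRUE))
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lambda_grid, standardize = FALSE)
  function(newx)
    stats::predict(fit, newx, type = "response")[, best]
}

binary_metrics <- function(prob, y_positive) {
  pred <- prob >= 0.5
  tp <- sum(pred & y_positive)
  fp <- sum(pred & !y_positive)
  fn <- sum(!pred & y_positive)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(roc_auc = roc_auc(prob, y_positive), precision = precision,
    recall = recall, f1 = f1)
}

#' Cross-validated signature classifier under one of three scenarios
#'
#' Runs a stratified k-fold cross-validated L2 logistic regression on a
#' signature feature matrix under one of three multicollinearity scenarios:
#' `"all_genes"` uses every feature; `"decollinear_per_fold"` re-selects a
#' decollinearized subset ([select_noncollinear()]) inside each training
#' fold; `"fold_stable_subset"` first computes the per-fold decollinear
#' sets, intersects them, and reruns the CV on the fixed intersection.
#' In every fold, standardization (mean 0, unit variance), SMOTE balancing
#' and feature selection are fit on the training portion only — the
#' held-out fold never leaks into them. The regularization strength is
#' grid-searched by inner stratified CV on ROC AUC.
#'
#' @param x samples x features matrix (a signature-restricted expression
#'   matrix, samples in rows).
#' @param y binary labels (factor; second level is scored as positive).
#' @param scenario one of `"all_genes"`, `"decollinear_per_fold"`,
#'   `"fold_stable_subset"`.
#' @param n_folds folds (default 10).
#' @param threshold decollinearity correlation threshold (default 0.4).
#' @param k_neighbors SMOTE neighbours (default 5).
#' @param lambda_grid L2 regularization grid.
#' @param seed integer seed (folds, SMOTE, inner CV).
#' @return object of class `cv_result`: `metrics` (mean and sd of ROC AUC,
#'   precision, recall, F1 over folds), `per_fold` (n_folds x 4),
#'   `features_per_fold`, `scenario`, and for scenario 3 `stable_features`.
#' @export
run_scenario <- function(x, y, scenario = c("all_genes",
                                            "decollinear_per_fold",
                                            "fold_stable_subset"),
                         n_folds = 10, threshold = 0.4, k_neighbors = 5,
                         lambda_grid = 10^seq(-4, 1, length.out = 8),
                         seed = 1L) {
  scenario <- match.arg(scenario)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("labels must be binary")

  if (scenario == "fold_stable_subset") {
    pre <- run_scenario(x, y, "decollinear_per_fold", n_folds = n_folds,
                        threshold = threshold, k_neighbors = k_neighbors,
                        lambda_grid = lambda_grid, seed = seed)
    stable <- Reduce(intersect, pre$features_per_fold)
    if (length(stable) == 0)
      stop("no features survive in every fold (per-fold set sizes: ",
           paste(lengths(pre$features_per_fold), collapse = ", "), ")")
    out <- run_scenario(x[, stable, drop = FALSE], y, "all_genes",
                        n_folds = n_folds, k_neighbors = k_neighbors,
                        lambda_grid = lambda_grid, seed = seed)
    out$scenario <- "fold_stable_subset"
    out$stable_features <- stable
    out$features_per_fold <- pre$features_per_fold
    return(out)
  }

  folds <- stratified_folds(y, n_folds = n_folds, seed = seed)
  pos <- levels(y)[2]
  per_fold <- matrix(NA_real_, n_folds, 4,
                     dimnames = list(NULL, c("roc_auc", "precision",
                                             "recall", "f1")))
  features_per_fold <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    te <- folds[[f]]
    xtr <- x[-te, , drop = FALSE]
    ytr <- y[-te]
    mu <- colMeans(xtr)
    sd_ <- apply(xtr, 2, stats::sd)
    sd_[sd_ == 0] <- 1
    xtr <- sweep(sweep(xtr, 2, mu), 2, sd_, `/`)
    xte <- sweep(sweep(x[te, , drop = FALSE], 2, mu), 2, sd_, `/`)
    bal <- smote_oversample(xtr, ytr, k_neighbors = k_neighbors,
                            seed = seed + f)
    feats <- colnames(x)
    if (scenario == "decollinear_per_fold") {
      feats <- select_noncollinear(bal$x, bal$y, threshold = threshold)
      bal$x <- bal$x[, feats, drop = FALSE]
      xte <- xte[, feats, drop = FALSE]
    }
    features_per_fold[[f]] <- feats
    model <- fit_l2_logistic(bal$x, bal$y, lambda_grid = lambda_grid,
                             seed = seed + f)
    per_fold[f, ] <- binary_metrics(model(xte), y[te] == pos)
  }
  structure(list(
    metrics = data.frame(metric = colnames(per_fold),
                         mean = colMeans(per_fold),
                         sd = apply(per_fold, 2, stats::sd),
                         row.names = NULL),
    per_fold = per_fold, features_per_fold = features_per_fold,
    scenario = scenario), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result, scenario:", x$scenario, "\n")
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-9s %.3f +/- %.3f\n", m$metric[i], m$mean[i], m$sd[i]))
  invisible(x)
}

#' Random-gene baseline classifiers
#'
#' Repeats [run_scenario()] on `n_classifiers` independent draws of
#' `n_genes_per_draw` genes sampled without replacement from the full
#' matrix (optionally excluding a gene set, e.g. the signature under test)
#' and averages the metrics. On data whose signal lives only in the
#' excluded signature, this baseline should sit at chance.
#'
#' @param x samples x genes matrix (the full transformed matrix).
#' @param y binary labels.
#' @param n_genes_per_draw genes per draw (default 131).
#' @param n_classifiers number of draws (default 10).
#' @param exclude gene IDs excluded from the sampling pool.
#' @param seed integer seed.
#' @param ... passed to [run_scenario()].
#' @return object of class `cv_result` (means over classifiers; sd column
#'   is the between-classifier sd), plus `per_classifier`.
#' @export
random_gene_baseline <- function(x, y, n_genes_per_draw = 131,
                                 n_classifiers = 10, exclude = NULL,
                                 seed = 1L, ...) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  pool <- setdiff(colnames(x), exclude)
  if (length(pool) < n_genes_per_draw)
    stop("not enough genes in the sampling pool")
  set.seed(seed)
  draw_seeds <- sample.int(.Machine$integer.max - 1, n_classifiers)
  per <- matrix(NA_real_, n_classifiers, 4,
                dimnames = list(NULL, c("roc_auc", "precision", "recall",
                                        "f1")))
  draws <- vector("list", n_classifiers)
  for (i in seq_len(n_classifiers)) {
    set.seed(draw_seeds[i])
    genes <- sample(pool, n_genes_per_draw)
    draws[[i]] <- genes
    res <- run_scenario(x[, genes, drop = FALSE], y, seed = draw_seeds[i],
                        ...)
    per[i, ] <- res$metrics$mean
  }
  structure(list(
    metrics = data.frame(metric = colnames(per), mean = colMeans(per),
                         sd = apply(per, 2, stats::sd), row.names = NULL),
    per_classifier = per, draws = draws, scenario = "random_gene_baseline"),
    class = "cv_result")
}
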