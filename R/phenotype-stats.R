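#' Construct a contingency table of observed counts
#'
#' @param observed non-negative integer matrix (categories x clusters) with
#'   at least 2 rows and 2 columns and positive marginals.
#' @param row_labels,col_labels optional dimension labels.
#' @return object of class `contingency_table`.
#' @export
contingency_table <- function(observed, row_labels = rownames(observed),
                              col_labels = colnames(observed)) {
  observed <- as.matrix(observed)
  if (any(observed < 0) || any(observed != round(observed)))
    stop("observed counts must be non-negative integers")
  if (nrow(observed) < 2 || ncol(observed) < 2)
    stop("need at least 2 rows and 2 columns")
  dimnames(observed) <- list(
    row_labels %||% paste0("row", seq_len(nrow(observed))),
    col_labels %||% paste0("cluster", seq_len(ncol(observed))))
  structure(list(observed = observed), class = "contingency_table")
}

#' Build a 2 x k table from per-cluster positives and totals
#'
#' Row one holds the positive counts, row two the complements
#' (`totals - positives`) — the construction used to test whether one
#' phenotype category (e.g. C9orf72 carriers, bulbar onset) is distributed
#' evenly across clusters.
#'
#' @param positives per-cluster positive counts.
#' @param totals per-cluster totals (elementwise >= positives).
#' @param category name for the positive row (default "positive").
#' @param col_labels cluster labels.
#' @return a [contingency_table()].
#' @export
build_binary_table <- function(positives, totals, category = "positive",
                               col_labels = NULL) {
  if (length(positives) != length(totals))
    stop("positives and totals must have the same length")
  if (any(positives > totals))
    stop("positives exceed totals")
  contingency_table(rbind(positives, totals - positives),
                    row_labels = c(category, paste0("not_", category)),
                    col_labels = col_labels %||%
                      paste0("cluster", seq_along(totals)))
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson statistic `sum((O - E)^2 / E)` with expected counts from
#' the product of the margins, no continuity correction, and the p-value
#' from the upper tail of the chi-square distribution with
#' `(r - 1)(c - 1)` degrees of freedom.
#'
#' @param table a [contingency_table()] (or plain count matrix).
#' @return object of class `chi_square_result`: `statistic`, `df`,
#'   `p_value`, `expected`.
#' @export
chi_square_independence <- function(table) {
  obs <- if (inherits(table, "contingency_table")) table$observed
    else contingency_table(table)$observed
  rs <- rowSums(obs)
  cs <- colSums(obs)
  if (any(rs == 0) || any(cs == 0))
    stop("zero row or column marginal; the test is undefined")
  n <- sum(obs)
  expected <- outer(rs, cs) / n
  statistic <- sum((obs - expected)^2 / expected)
  df <- (nrow(obs) - 1) * (ncol(obs) - 1)
  structure(list(statistic = statistic, df = df,
                 p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
                 expected = expected, observed = obs),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("chi-square test of independence: X2 = %.2f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Published cluster-phenotype contingency tables
#'
#' The per-cluster phenotype counts of the four ALS case cohorts this
#' package's statistics were designed around (motor-cortex discovery and
#' replication cohorts plus two blood cohorts), as 2 x k and 2 x 3 tables
#' ready for [chi_square_independence()]. Each element carries a
#' `published` attribute with the originally reported statistic and
#' p-value. The discovery-cohort limb-onset table is included for
#' completeness but its published statistic (6.05) is not reproduced by
#' this 2 x 3 construction (which gives 7.22), unlike every other table;
#' see the package vignette.
#'
#' @return named list of [contingency_table()] objects.
#' @export
als_contingency_tables <- function() {
  tab <- function(pos, tot, category, stat, p) {
    t <- build_binary_table(pos, tot, category = category)
    attr(t, "published") <- c(statistic = stat, p_value = p)
    t
  }
  kcl <- c(60, 28, 24); tals <- c(97, 28, 43)
  zucca <- c(13, 1, 1); vanr <- c(335, 33, 29)
  out <- list(
    kcl_sex = tab(c(35, 15, 15), kcl, "male", 0.43, 0.81),
    kcl_c9 = tab(c(7, 1, 0), kcl, "c9_positive", 4.24, 0.12),
    kcl_limb = tab(c(36, 10, 17), kcl, "limb_onset", 6.05, 0.05),
    kcl_bulbar = tab(c(15, 7, 5), kcl, "bulbar_onset", 0.18, 0.91),
    kcl_limb_bulbar = tab(c(1, 1, 0), kcl, "limb_bulbar_onset", 0.95, 0.62),
    targetals_sex = tab(c(60, 18, 21), tals, "male", 2.48, 0.29),
    targetals_c9 = tab(c(11, 0, 4), tals, "c9_positive", 3.45, 0.18),
    targetals_limb = tab(c(65, 22, 17), tals, "limb_onset", 13.49, 1.2e-3),
    targetals_bulbar = tab(c(14, 5, 21), tals, "bulbar_onset", 20.10,
                           4.3e-5),
    targetals_limb_bulbar = tab(c(7, 0, 1), tals, "limb_bulbar_onset",
                                3.25, 0.20),
    zucca_sex = tab(c(6, 0, 1), zucca, "male", 2.02, 0.36),
    vanrheenen_sex = tab(c(205, 18, 16), vanr, "male", 0.88, 0.64))
  # limb vs bulbar onset in the microarray blood cohort: a direct 2 x 3 of
  # the two onset rows, not a category-vs-complement table
  vr_onset <- contingency_table(rbind(limb = c(215, 21, 15),
                                      bulbar = c(120, 12, 14)),
                                col_labels = paste0("cluster", 1:3))
  attr(vr_onset, "published") <- c(statistic = 1.78, p_value = 0.41)
  out$vanrheenen_onset <- vr_onset
  out
}

#' One-way ANCOVA for a cluster effect
#'
#' Least-squares linear model of the outcome on covariates plus the cluster
#' factor; the cluster F statistic compares the full model with the reduced
#' model omitting only the cluster dummies:
#' `F = ((RSS_red - RSS_full) / (k - 1)) / (RSS_full / (n - p_full))`.
#' Rows with missing values are dropped listwise (and counted).
#'
#' @param outcome numeric outcome vector.
#' @param cluster per-sample cluster labels.
#' @param covariates optional data.frame of covariates (e.g. sex).
#' @return object of class `ancova_result`: `F`, `p_value`, `df`,
#'   `adjusted_means` (cluster means at covariate means), `residual_var`,
#'   `residual_df`, `group_sizes`, `n_dropped`, `transform_applied`.
#' @export
ancova_oneway <- function(outcome, cluster, covariates = NULL) {
  cluster <- as.factor(cluster)
  if (nlevels(cluster) < 2) stop("need at least 2 clusters")
  df <- data.frame(.y = outcome, .cluster = cluster)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  df$.cluster <- droplevels(df$.cluster)
  if (nlevels(df$.cluster) < 2 || any(table(df$.cluster) < 2))
    stop("each cluster needs at least 2 complete observations")
  cov_terms <- setdiff(names(df), c(".y", ".cluster"))
  rhs_red <- if (length(cov_terms)) paste(cov_terms, collapse = " + ")
    else "1"
  full <- stats::lm(stats::as.formula(paste(".y ~", rhs_red, "+ .cluster")),
                    data = df)
  if (any(is.na(stats::coef(full))))
    stop("rank-deficient design; aliased: ",
         paste(names(stats::coef(full))[is.na(stats::coef(full))],
               collapse = ", "))
  reduced <- stats::lm(stats::as.formula(paste(".y ~", rhs_red)), data = df)
  rss_f <- sum(stats::residuals(full)^2)
  rss_r <- sum(stats::residuals(reduced)^2)
  k <- nlevels(df$.cluster)
  df1 <- k - 1
  df2 <- full$df.residual
  Fstat <- ((rss_r - rss_f) / df1) / (rss_f / df2)
  # adjusted means: predictions at the covariate means (numeric) or the
  # observed covariate distribution (factors), per cluster
  newdata <- df[rep(1, k), , drop = FALSE]
  newdata$.cluster <- factor(levels(df$.cluster),
                             levels = levels(df$.cluster))
  for (v in cov_terms) {
    if (is.numeric(df[[v]])) newdata[[v]] <- mean(df[[v]])
    else newdata[[v]] <- factor(names(which.max(table(df[[v]]))),
                                levels = levels(as.factor(df[[v]])))
  }
  adj <- stats::predict(full, newdata)
  structure(list(F = Fstat, p_value = stats::pf(Fstat, df1, df2,
                                                lower.tail = FALSE),
                 df = c(df1, df2),
                 adjusted_means = stats::setNames(adj, levels(df$.cluster)),
                 residual_var = rss_f / df2, residual_df = df2,
                 group_sizes = table(df$.cluster),
                 n_dropped = sum(!keep), model = full,
                 transform_applied = "none"),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("one-way ANCOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df[1], x$df[2], x$F, x$p_value))
  invisible(x)
}

#' Tukey HSD post-hoc pairwise comparisons
#'
#' Studentized-range test on the (covariate-adjusted) cluster means of a
#' fitted ANCOVA: `q = |m_i - m_j| / sqrt(s^2 / 2 * (1/n_i + 1/n_j))`
#' (Tukey-Kramer for unequal group sizes), with the p-value from the
#' studentized range distribution with `k` groups and the model's residual
#' degrees of freedom.
#'
#' @param ancova an `ancova_result`, or NULL if the raw pieces are given.
#' @param means,group_sizes,residual_var,residual_df raw inputs used when
#'   `ancova` is NULL.
#' @return data.frame with one row per pair: `group1`, `group2`, `diff`,
#'   `q`, `p_adj`.
#' @export
tukey_hsd <- function(ancova = NULL, means = NULL, group_sizes = NULL,
                      residual_var = NULL, residual_df = NULL) {
  if (!is.null(ancova)) {
    means <- ancova$adjusted_means
    group_sizes <- as.numeric(ancova$group_sizes)
    residual_var <- ancova$residual_var
    residual_df <- ancova$residual_df
  }
  k <- length(means)
  if (k < 2) stop("need at least 2 groups")
  labs <- names(means) %||% as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  out <- data.frame(group1 = labs[pairs[1, ]], group2 = labs[pairs[2, ]],
                    diff = NA_real_, q = NA_real_, p_adj = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(residual_var / 2 * (1 / group_sizes[a] + 1 / group_sizes[b]))
    q <- abs(means[a] - means[b]) / se
    out$diff[i] <- means[a] - means[b]
    out$q[i] <- q
    out$p_adj[i] <- stats::ptukey(q, nmeans = k, df = residual_df,
                                  lower.tail = FALSE)
  }
  out
}

#' Shapiro-Wilk-gated log transformation
#'
#' Tests the values for normality with the Shapiro-Wilk test; when
#' `p < alpha` the natural-log transform is applied. Values <= 0 under a
#' required transform raise an error (no silent shifting), as does a
#' constant vector (the test is undefined).
#'
#' @param values numeric vector, `n >= 3`.
#' @param alpha gate level (default 0.05).
#' @return list with `values` (possibly transformed), `decision`
#'   (`"keep"` or `"log"`), `shapiro_p`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("need at least 3 non-missing values")
  if (stats::sd(values) == 0)
    stop("constant vector: the Shapiro-Wilk test is undefined")
  p <- stats::shapiro.test(values)$p.value
  if (p >= alpha)
    return(list(values = values, decision = "keep", shapiro_p = p))
  if (any(values <= 0))
    stop("log transform required (Shapiro-Wilk p = ", signif(p, 3),
         ") but values are not all positive; transform or rescale upstream")
  list(values = log(values), decision = "log", shapiro_p = p)
}
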