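#' Default cluster-conditional phenotype model
#'
#' Per-cluster categorical probabilities (sex, onset site, C9orf72 carrier
#' status) and per-cluster normal parameters for continuous phenotypes.
#' The defaults mirror the demographic structure of a three-cluster
#' motor-cortex ALS case cohort: cluster one enriched for C9orf72 carriers
#' and earlier onset, cluster two with later onset and longer survival.
#'
#' @param k_clusters number of clusters the model must cover.
#' @return list with elements `sex_male_prob`, `c9_prob`, `onset_probs`
#'   (k x 3 matrix: limb, bulbar, limb_bulbar), `age_onset` (k x 2 matrix:
#'   mean, sd in years), `duration_meanlog`, `duration_sdlog` (log-normal
#'   disease duration in years).
#' @export
default_phenotype_model <- function(k_clusters = 3) {
  base <- list(
    sex_male_prob = c(35 / 60, 15 / 28, 15 / 24),
    c9_prob = c(7 / 60, 1 / 28, 0),
    onset_probs = rbind(c(36, 15, 1) / 52, c(10, 7, 1) / 18, c(17, 5, 0) / 22),
    age_onset = rbind(c(58.8, 11.6), c(65.7, 12.3), c(61.7, 15.7)),
    duration_meanlog = log(c(3.16, 2.30, 2.38)),
    duration_sdlog = c(0.5, 0.5, 0.5))
  if (k_clusters == 3) return(base)
  idx <- rep_len(seq_len(3), k_clusters)
  list(sex_male_prob = base$sex_male_prob[idx],
       c9_prob = base$c9_prob[idx],
       onset_probs = base$onset_probs[idx, , drop = FALSE],
       age_onset = base$age_onset[idx, , drop = FALSE],
       duration_meanlog = base$duration_meanlog[idx],
       duration_sdlog = base$duration_sdlog[idx])
}

#' Configuration of the synthetic expression generator
#'
#' Defines the statistical model every synthetic dataset is drawn from:
#' per-gene log-normal baseline means, log-normal library-size factors,
#' negative-binomial counts with variance `mu + alpha * mu^2`, and `k`
#' planted sample clusters, each marked by a disjoint block of
#' `signature_size` genes up-regulated by `2^log2_fold_change` in its own
#' cluster. Defaults emulate a motor-cortex case cohort with three clusters
#' of relative size 60:28:24.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param k_clusters number of planted clusters.
#' @param signature_size signature genes per cluster (disjoint blocks).
#' @param log2_fold_change log2 effect of a signature gene in its own
#'   cluster; > 0. The discovery cohorts this emulates publish no effect
#'   size, so this is a free parameter (default 2).
#' @param nb_dispersion negative-binomial dispersion alpha >= 0
#'   (variance `mu + alpha mu^2`); 0 gives Poisson counts.
#' @param libsize_log_sd sd of log-normal library-size factors (>= 0).
#' @param baseline_log_mean,baseline_log_sd log-normal parameters of the
#'   per-gene baseline means.
#' @param cluster_proportions simplex vector of length `k_clusters`.
#' @param phenotype_model see [default_phenotype_model()].
#' @param xym_fraction fraction of genes assigned to X/Y/MT chromosomes
#'   (exercises the autosome filter).
#' @param seed integer seed; gene-level structure (baselines, signature
#'   blocks, chromosomes) is drawn from this seed so that matched
#'   validation/control datasets share the same gene model.
#' @return validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 2000, n_samples = 120, k_clusters = 3,
                             signature_size = 50, log2_fold_change = 2,
                             nb_dispersion = 0.2, libsize_log_sd = 0.2,
                             baseline_log_mean = log(50), baseline_log_sd = 1,
                             cluster_proportions = c(60, 28, 24) / 112,
                             phenotype_model = default_phenotype_model(k_clusters),
                             xym_fraction = 0.06, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              k_clusters = as.integer(k_clusters),
              signature_size = as.integer(signature_size),
              log2_fold_change = log2_fold_change,
              nb_dispersion = nb_dispersion, libsize_log_sd = libsize_log_sd,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              cluster_proportions = cluster_proportions,
              phenotype_model = phenotype_model,
              xym_fraction = xym_fraction, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1, cfg$n_samples >= 1, cfg$k_clusters >= 1,
            cfg$signature_size >= 1)
  if (length(cfg$cluster_proportions) != cfg$k_clusters)
    stop("cluster_proportions must have length k_clusters")
  if (any(cfg$cluster_proportions < 0) ||
      abs(sum(cfg$cluster_proportions) - 1) > 1e-12)
    stop("cluster_proportions must be a simplex vector (sum 1 within 1e-12)")
  if (cfg$signature_size * cfg$k_clusters > cfg$n_genes)
    stop("signature_size x k_clusters exceeds n_genes")
  if (cfg$log2_fold_change < 0) stop("log2_fold_change must be >= 0")
  if (cfg$nb_dispersion < 0 || cfg$libsize_log_sd < 0 ||
      cfg$baseline_log_sd < 0)
    stop("variance parameters must be >= 0")
  invisible(cfg)
}

# Gene-level model shared by discovery, validation and control datasets:
# baseline means, disjoint signature blocks, chromosome labels. Drawn from
# config$seed only, so matched datasets agree gene-by-gene.
gene_model <- function(cfg) {
  set.seed(cfg$seed)
  gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
  base_means <- exp(rnorm(cfg$n_genes, cfg$baseline_log_mean,
                          cfg$baseline_log_sd))
  sig_pool <- sample.int(cfg$n_genes, cfg$signature_size * cfg$k_clusters)
  signatures <- split(gene_ids[sig_pool],
                      rep(seq_len(cfg$k_clusters), each = cfg$signature_size))
  names(signatures) <- paste0("cluster", seq_len(cfg$k_clusters))
  n_xym <- round(cfg$xym_fraction * cfg$n_genes)
  chrom <- rep_len(as.character(1:22), cfg$n_genes)
  if (n_xym > 0) {
    # keep signature genes autosomal so the filter never deletes the signal
    nonsig <- setdiff(seq_len(cfg$n_genes), sig_pool)
    xym_idx <- sample(nonsig, min(n_xym, length(nonsig)))
    chrom[xym_idx] <- rep_len(c("X", "Y", "MT"), length(xym_idx))
  }
  list(gene_ids = gene_ids, base_means = base_means,
       signatures = signatures, sig_index = sig_pool, chromosome = chrom)
}

# Deterministic cluster sizes from proportions (largest-remainder rounding),
# then a shuffled label vector.
planted_labels <- function(props, n) {
  raw <- props * n
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    add <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[add] <- sizes[add] + 1
  }
  sample(rep(seq_along(props), times = sizes))
}

# Negative-binomial draw with variance mu + alpha mu^2 (Poisson if alpha=0).
rcounts <- function(n, mu, alpha) {
  if (alpha == 0) rpois(n, mu) else rnbinom(n, size = 1 / alpha, mu = mu)
}

nb_matrix <- function(gm, cfg, labels, libsize, gene_idx = NULL,
                      platform_shift = NULL) {
  gi <- if (is.null(gene_idx)) seq_along(gm$gene_ids) else gene_idx
  mu <- matrix(gm$base_means[gi], nrow = length(gi), ncol = length(labels))
  if (!is.null(labels) && cfg$log2_fold_change > 0) {
    fc <- 2^cfg$log2_fold_change
    for (j in seq_len(cfg$k_clusters)) {
      rows <- which(gm$gene_ids[gi] %in% gm$signatures[[j]])
      cols <- which(labels == j)
      if (length(rows) && length(cols)) mu[rows, cols] <- mu[rows, cols] * fc
    }
  }
  mu <- sweep(mu, 2, libsize, `*`)
  if (!is.null(platform_shift)) mu <- mu * platform_shift
  counts <- matrix(rcounts(length(mu), as.vector(mu), cfg$nb_dispersion),
                   nrow = nrow(mu))
  counts
}

generate_phenotype <- function(cfg, labels, sample_ids) {
  pm <- cfg$phenotype_model
  n <- length(labels)
  sex <- ifelse(runif(n) < pm$sex_male_prob[labels], "M", "F")
  c9 <- as.integer(runif(n) < pm$c9_prob[labels])
  onset_site <- vapply(labels, function(j)
    sample(c("limb", "bulbar", "limb_bulbar"), 1,
           prob = pm$onset_probs[j, ]), character(1))
  age_onset <- rnorm(n, pm$age_onset[labels, 1], pm$age_onset[labels, 2])
  duration <- exp(rnorm(n, pm$duration_meanlog[labels],
                        pm$duration_sdlog[labels]))
  data.frame(sample_id = sample_ids, cluster = labels, sex = sex,
             onset_site = onset_site, c9_status = c9,
             age_at_onset = age_onset, disease_duration = duration,
             age_at_death = age_onset + duration,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic discovery cohort
#'
#' Draws a genes x samples count matrix with `k` planted sample clusters,
#' each over-expressing its own disjoint block of signature genes by
#' `2^log2_fold_change`, negative-binomial noise and log-normal library-size
#' variation, plus a matched cluster-conditional phenotype table. Fully
#' reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return [expression_dataset()] with `truth` (labels, signatures,
#'   library-size factors) and a `phenotype` data.frame.
#' @export
generate_discovery <- function(config) {
  validate_synthetic_config(config)
  gm <- gene_model(config)          # consumes config$seed
  labels <- planted_labels(config$cluster_proportions, config$n_samples)
  libsize <- exp(rnorm(config$n_samples, 0, config$libsize_log_sd))
  counts <- nb_matrix(gm, config, labels, libsize)
  sample_ids <- sprintf("sample%03d", seq_len(config$n_samples))
  pheno <- generate_phenotype(config, labels, sample_ids)
  expression_dataset(counts, gm$gene_ids, sample_ids,
                     chromosome = gm$chromosome, data_kind = "counts",
                     truth = list(labels = labels, signatures = gm$signatures,
                                  libsize = libsize,
                                  base_means = gm$base_means),
                     phenotype = pheno, config = config)
}

#' Generate a matched validation cohort on a restricted gene set
#'
#' New samples from the same planted cluster model as a discovery dataset,
#' observed on a random subset of genes (emulating a different platform or
#' annotation) with an optional per-gene multiplicative platform shift.
#'
#' @param discovery an [expression_dataset()] produced by
#'   [generate_discovery()] (must carry `truth` and `config`).
#' @param gene_keep_fraction fraction of genes observed, in (0, 1].
#' @param platform_shift_sd sd of a per-gene log-normal multiplicative
#'   shift (>= 0; 0 disables the shift).
#' @param n_samples number of new samples.
#' @param seed integer seed for the sample-level draws.
#' @return [expression_dataset()] with planted `truth`.
#' @export
generate_validation <- function(discovery, gene_keep_fraction = 1,
                                platform_shift_sd = 0, n_samples = 100,
                                seed = 1L) {
  if (is.null(discovery$truth) || is.null(discovery$config))
    stop("discovery dataset must carry planted truth and its config")
  if (gene_keep_fraction <= 0 || gene_keep_fraction > 1)
    stop("gene_keep_fraction must be in (0, 1]")
  cfg <- discovery$config
  gm <- gene_model(cfg)             # regenerate shared gene model
  set.seed(seed)
  n_keep <- round(gene_keep_fraction * cfg$n_genes)
  keep <- if (gene_keep_fraction == 1) seq_len(cfg$n_genes) else
    sort(sample.int(cfg$n_genes, n_keep))
  per_sig <- vapply(gm$signatures, function(s)
    sum(gm$gene_ids[keep] %in% s), integer(1))
  if (any(per_sig < 2))
    stop("gene_keep_fraction leaves fewer than 2 genes in a signature")
  labels <- planted_labels(cfg$cluster_proportions, n_samples)
  libsize <- exp(rnorm(n_samples, 0, cfg$libsize_log_sd))
  shift <- if (platform_shift_sd > 0)
    exp(rnorm(length(keep), 0, platform_shift_sd)) else NULL
  counts <- nb_matrix(gm, cfg, labels, libsize, gene_idx = keep,
                      platform_shift = shift)
  sample_ids <- sprintf("vsample%03d", seq_len(n_samples))
  pheno <- generate_phenotype(cfg, labels, sample_ids)
  expression_dataset(counts, gm$gene_ids[keep], sample_ids,
                     chromosome = gm$chromosome[keep], data_kind = "counts",
                     truth = list(labels = labels, signatures = gm$signatures,
                                  libsize = libsize),
                     phenotype = pheno, config = cfg)
}

#' Generate a signature-free control cohort
#'
#' Samples drawn from the baseline model of a configuration with no
#' signature effect: all samples are exchangeable, so no planted labels are
#' stored. Shares the gene-level model (baseline means, chromosomes) with
#' discovery/validation datasets generated from the same config.
#'
#' @param config a [synthetic_config()].
#' @param n_samples number of control samples.
#' @param seed integer seed for the sample-level draws.
#' @return [expression_dataset()]; `truth$labels` is `NULL`.
#' @export
generate_control <- function(config, n_samples = 60, seed = 2L) {
  validate_synthetic_config(config)
  gm <- gene_model(config)
  set.seed(seed)
  libsize <- exp(rnorm(n_samples, 0, config$libsize_log_sd))
  counts <- nb_matrix(gm, config, labels = rep(0L, n_samples),
                      libsize = libsize)
  sample_ids <- sprintf("control%03d", seq_len(n_samples))
  expression_dataset(counts, gm$gene_ids, sample_ids,
                     chromosome = gm$chromosome, data_kind = "counts",
                     truth = list(labels = NULL,
                                  base_means = gm$base_means),
                     config = config)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes `expression.tsv` (genes as rows, header = sample IDs),
#' `annotation.tsv` (gene_id, chromosome), `phenotype.csv` if present, and
#' `truth.json` with planted labels and signature gene lists.
#'
#' @param data an [expression_dataset()].
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of file paths written.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             annotation = file.path(dir, "annotation.tsv"))
  write_expression(data, paths[["expression"]])
  utils::write.table(
    data.frame(gene_id = data$gene_ids,
               chromosome = if (is.null(data$chromosome)) NA
                            else data$chromosome),
    paths[["annotation"]], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(data$phenotype)) {
    paths <- c(paths, phenotype = file.path(dir, "phenotype.csv"))
    utils::write.csv(data$phenotype, paths[["phenotype"]], row.names = FALSE)
  }
  if (!is.null(data$truth)) {
    paths <- c(paths, truth = file.path(dir, "truth.json"))
    jsonlite::write_json(
      list(labels = data$truth$labels, signatures = data$truth$signatures),
      paths[["truth"]], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}
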