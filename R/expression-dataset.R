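#' Construct an expression dataset
#'
#' The basic container of the package: a non-negative genes x samples matrix
#' together with gene/sample identifiers, per-gene chromosome labels and a
#' flag saying whether the values are raw counts or an already-normalized
#' (e.g. log-intensity) matrix. Simulated datasets additionally carry a
#' `truth` list with the planted sample labels and signature gene sets.
#'
#' @param values numeric genes x samples matrix, no negative entries.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param sample_ids character vector of unique sample identifiers (columns).
#' @param chromosome per-gene chromosome label ("1".."22", "X", "Y", "MT").
#' @param data_kind `"counts"` (non-negative integers) or `"normalized"`.
#' @param truth optional list with planted ground truth (simulations only):
#'   `labels` (per-sample cluster index), `signatures` (list of gene-ID
#'   vectors per cluster), and any generator-internal quantities.
#' @param phenotype optional per-sample phenotype `data.frame`.
#' @param config optional [synthetic_config()] the dataset was generated from.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, gene_ids = rownames(values),
                               sample_ids = colnames(values),
                               chromosome = NULL,
                               data_kind = c("counts", "normalized"),
                               truth = NULL, phenotype = NULL, config = NULL) {
  data_kind <- match.arg(data_kind)
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene_ids and sample_ids are required (or set as dimnames)")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids))
    stop("matrix dimensions do not match the ID vectors")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids")
  if (anyNA(values)) stop("values contain NA")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (data_kind == "counts" && any(values != round(values)))
    stop("counts mode requires integer values")
  if (!is.null(chromosome)) {
    chromosome <- as.character(chromosome)
    if (length(chromosome) != length(gene_ids))
      stop("chromosome must have one label per gene")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         chromosome = chromosome, data_kind = data_kind, truth = truth,
         phenotype = phenotype, config = config,
         genes_removed = list()),
    class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$data_kind))
  if (!is.null(x$truth$labels))
    cat(sprintf("  planted clusters: %s\n",
                paste(table(x$truth$labels), collapse = "/")))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

# Subset an expression dataset by gene and/or sample index, keeping
# annotation and truth labels consistent.
subset_dataset <- function(data, genes = NULL, samples = NULL) {
  gi <- if (is.null(genes)) seq_along(data$gene_ids) else genes
  si <- if (is.null(samples)) seq_along(data$sample_ids) else samples
  out <- data
  out$values <- data$values[gi, si, drop = FALSE]
  out$gene_ids <- data$gene_ids[gi]
  out$sample_ids <- data$sample_ids[si]
  if (!is.null(data$chromosome)) out$chromosome <- data$chromosome[gi]
  if (!is.null(data$truth$labels)) out$truth$labels <- data$truth$labels[si]
  if (!is.null(data$phenotype)) out$phenotype <- data$phenotype[si, , drop = FALSE]
  out
}
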