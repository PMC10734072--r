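#' Median-of-ratios size factors
#'
#' Per-sample library-size factors computed with the median-of-ratios
#' estimator: the reference for each gene is its geometric mean across
#' samples (genes with any zero count are excluded from the reference), and
#' each sample's factor is the median ratio of its counts to the reference,
#' rescaled so the geometric mean of the factors is 1.
#'
#' @param counts an [expression_dataset()] with `data_kind = "counts"`,
#'   or a plain non-negative matrix.
#' @return named numeric vector of positive size factors, geometric mean 1.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "expression_dataset")) {
    if (counts$data_kind != "counts")
      stop("size_factors requires raw counts")
    counts$values
  } else as.matrix(counts)
  if (any(m < 0)) stop("negative counts")
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos))
    stop("median-of-ratios requires at least one gene with non-zero ",
         "counts in every sample")
  log_ref <- rowMeans(log(m[all_pos, , drop = FALSE]))
  sf <- apply(m[all_pos, , drop = FALSE], 2, function(x)
    exp(stats::median(log(x) - log_ref)))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(m))
}

#' Remove lowly expressed and non-autosomal genes
#'
#' Retains genes whose total count across samples is at least
#' `min_total_count` and whose chromosome is one of "1".."22". Every removed
#' gene is recorded with its reason in the dataset's `genes_removed` ledger.
#'
#' @param data an [expression_dataset()].
#' @param min_total_count minimum total count across samples (default 10).
#' @param annotation optional named character vector gene_id -> chromosome;
#'   defaults to the dataset's own `chromosome` field.
#' @param missing_annotation `"error"` or `"drop"` for genes without a
#'   chromosome label.
#' @return filtered [expression_dataset()] with a populated `genes_removed`
#'   list (`low_expression`, `non_autosomal`, `no_annotation`).
#' @export
filter_genes <- function(data, min_total_count = 10, annotation = NULL,
                         missing_annotation = c("error", "drop")) {
  missing_annotation <- match.arg(missing_annotation)
  chrom <- if (!is.null(annotation)) {
    unname(annotation[data$gene_ids])
  } else data$chromosome
  if (is.null(chrom)) stop("no chromosome annotation available")
  miss <- is.na(chrom)
  if (any(miss) && missing_annotation == "error")
    stop("missing chromosome annotation for ",
         paste(utils::head(data$gene_ids[miss], 5), collapse = ", "))
  totals <- rowSums(data$values)
  low <- totals < min_total_count
  nonauto <- !miss & !(chrom %in% as.character(1:22))
  keep <- !(low | nonauto | miss)
  if (!any(keep)) stop("no genes survive filtering")
  out <- subset_dataset(data, genes = which(keep))
  out$genes_removed <- list(
    low_expression = data$gene_ids[low],
    non_autosomal = data$gene_ids[nonauto & !low],
    no_annotation = data$gene_ids[miss & !low])
  out
}

#' Variance-stabilizing transform (size-factor-scaled log2)
#'
#' Default transform: `log2(counts / sf + 1)` per sample. This is a
#' monotone, approximately variance-stabilizing transform of the normalized
#' counts; an alternative transform can be plugged in via `transform`.
#'
#' @param counts an [expression_dataset()] with counts, or a matrix.
#' @param sf per-sample size factors (defaults to [size_factors()]).
#' @param transform optional function `(normalized_matrix) -> matrix`
#'   replacing the default `log2(x + 1)`.
#' @return a `normalized_matrix` object: list with `values` (transformed
#'   genes x samples matrix), `size_factors`, and the `genes_removed`
#'   ledger carried over from the input.
#' @export
vst_transform <- function(counts, sf = NULL, transform = NULL) {
  is_ds <- inherits(counts, "expression_dataset")
  m <- if (is_ds) counts$values else as.matrix(counts)
  if (any(m < 0)) stop("negative counts")
  if (is.null(sf)) sf <- size_factors(counts)
  if (any(sf <= 0)) stop("size factors must be positive")
  norm <- sweep(m, 2, sf, `/`)
  v <- if (is.null(transform)) log2(norm + 1) else transform(norm)
  structure(list(values = v, size_factors = sf,
                 genes_removed = if (is_ds) counts$genes_removed else list()),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Plain median absolute deviation (no consistency constant): the ranking
# used for variable-gene selection is scale-invariant.
row_mad <- function(m) {
  apply(m, 1, function(x) stats::median(abs(x - stats::median(x))))
}

#' Select the most variably expressed genes
#'
#' Ranks genes by the median absolute deviation of their transformed
#' expression and returns the top `n_top` gene IDs. Ties are broken by
#' lexicographic gene ID so the selection is deterministic.
#'
#' @param matrix a `normalized_matrix` (or plain matrix with gene rownames).
#' @param n_top number of genes to return (default 5000); `NULL` returns
#'   all genes in variability order.
#' @return character vector of gene IDs, most variable first.
#' @export
select_variable_genes <- function(matrix, n_top = 5000) {
  m <- if (inherits(matrix, "normalized_matrix")) matrix$values else matrix
  if (is.null(n_top)) n_top <- nrow(m)   # NULL = keep all genes, ranked
  if (n_top < 1) stop("n_top must be >= 1")
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  if (n_top > nrow(m)) {
    warning("n_top exceeds the number of genes; returning all genes")
    n_top <- nrow(m)
  }
  mads <- row_mad(m)
  ids[order(-mads, ids)][seq_len(n_top)]
}

#' Full preprocessing stage
#'
#' Applies the standard sequence: gene filtering (low expression,
#' non-autosomal), median-of-ratios size factors, variance-stabilizing
#' transform, and variable-gene selection. Pre-normalized input
#' (`data_kind = "normalized"`, e.g. quantile-normalized log microarray
#' intensities) skips normalization and transformation and passes through
#' to gene selection directly.
#'
#' @param data an [expression_dataset()].
#' @param min_total_count see [filter_genes()].
#' @param n_top number of variable genes to retain (default 5000).
#' @param filter apply the gene filter (default TRUE; set FALSE when no
#'   annotation is available).
#' @return list with `matrix` (`normalized_matrix` restricted to the
#'   selected genes), `selected_genes`, `size_factors` (NULL in
#'   normalized mode), and `filtered` (the filtered dataset).
#' @export
preprocess <- function(data, min_total_count = 10, n_top = 5000,
                       filter = TRUE) {
  filtered <- if (filter) filter_genes(data, min_total_count) else data
  if (data$data_kind == "normalized") {
    nm <- structure(list(values = filtered$values, size_factors = NULL,
                         genes_removed = filtered$genes_removed),
                    class = "normalized_matrix")
  } else {
    sf <- size_factors(filtered)
    nm <- vst_transform(filtered, sf)
  }
  sel <- select_variable_genes(nm, n_top)
  nm_sel <- nm
  nm_sel$values <- nm$values[sel, , drop = FALSE]
  list(matrix = nm_sel, selected_genes = sel,
       size_factors = nm$size_factors, filtered = filtered)
}
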