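#' Read an expression matrix from disk
#'
#' Reads TSV/CSV (genes as rows, header = sample IDs, first column = gene
#' IDs) or MatrixMarket MTX (with gene/sample ID sidecar files, one ID per
#' line). Duplicate IDs and negative values are rejected with informative
#' errors; a samples-as-rows file can be ingested with
#' `orientation = "samples_rows"`.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format `"tsv"`, `"csv"` or `"mtx"`.
#' @param orientation `"genes_rows"` (canonical) or `"samples_rows"`.
#' @param gene_file,sample_file sidecar ID files (MTX only).
#' @param data_kind `"counts"`, `"normalized"`, or `"auto"` (counts iff all
#'   values are integers).
#' @param annotation optional named chromosome vector attached to the
#'   dataset.
#' @return an [expression_dataset()].
#' @export
read_expression <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                            orientation = c("genes_rows", "samples_rows"),
                            gene_file = NULL, sample_file = NULL,
                            data_kind = c("auto", "counts", "normalized"),
                            annotation = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  data_kind <- match.arg(data_kind)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     stop("cannot infer format from extension: ", path))
  if (format == "mtx") {
    if (is.null(gene_file) || is.null(sample_file))
      stop("MTX input requires gene_file and sample_file sidecars")
    m <- tryCatch(as.matrix(Matrix::readMM(path)), error = function(e)
      stop("failed to parse MTX file ", path, ": ", conditionMessage(e)))
    genes <- readLines(gene_file)
    samples <- readLines(sample_file)
    if (nrow(m) != length(genes) || ncol(m) != length(samples))
      stop(sprintf(paste0("MTX dimensions (%d x %d) do not match sidecar ",
                          "IDs (%d genes, %d samples)"),
                   nrow(m), ncol(m), length(genes), length(samples)))
    rownames(m) <- genes
    colnames(m) <- samples
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) {
      dup <- ids[duplicated(ids)][1]
      stop("duplicate row ID '", dup, "' at line ",
           which(ids == dup)[2] + 1L)
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric values in ", path)
    rownames(m) <- ids
  }
  if (orientation == "samples_rows") m <- t(m)
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at gene '%s', sample '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  if (data_kind == "auto")
    data_kind <- if (all(m == round(m))) "counts" else "normalized"
  chrom <- if (!is.null(annotation)) unname(annotation[rownames(m)]) else NULL
  expression_dataset(m, data_kind = data_kind, chromosome = chrom)
}

#' Write an expression matrix as TSV
#'
#' Canonical on-disk layout: genes as rows, first column `gene_id`, header
#' row of sample IDs, full precision.
#'
#' @param data an [expression_dataset()], `normalized_matrix`, or matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_expression <- function(data, path) {
  m <- if (inherits(data, "expression_dataset")) data$values
    else if (inherits(data, "normalized_matrix")) data$values
    else as.matrix(data)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(format(df, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table (gene_id, chromosome)
#'
#' @param path TSV with columns `gene_id` and `chromosome`.
#' @return named character vector gene_id -> chromosome.
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "chromosome") %in% names(df)))
    stop("annotation needs gene_id and chromosome columns")
  stats::setNames(as.character(df$chromosome), df$gene_id)
}
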