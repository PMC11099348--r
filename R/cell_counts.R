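#' Gene-by-cell count container
#'
#' Bundles a sparse integer count matrix with per-cell metadata. Rows are
#' genes, columns are cells. The metadata carries the treatment time point
#' (hours), a cell-line tag and the per-cell QC statistics used by
#' [filter_cells()]: unique read count, unique gene count and percent
#' mitochondrial reads.
#'
#' @param counts matrix or sparse Matrix of non-negative integers
#'   (gene x cell). Dimnames, if present, seed `genes`/`cell_meta$barcode`.
#' @param cell_meta data.frame with one row per cell. Must contain
#'   `time_h`; `cell_line`, `n_reads`, `n_genes`, `pct_mito` and `barcode`
#'   are filled with defaults when missing (`n_reads`/`n_genes` are
#'   derived from the matrix).
#' @param genes character vector of gene identifiers (defaults to
#'   rownames or `gene1..geneN`).
#'
#' @return An object of class `cell_counts`: a list with elements
#'   `matrix` (a `dgCMatrix`), `genes` and `cell_meta`.
#' @export
cell_counts <- function(counts, cell_meta, genes = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  v <- counts@x
  if (any(v < 0) || any(v != round(v))) {
    stopf("count matrix must contain non-negative integers")
  }
  if (is.null(genes)) {
    genes <- rownames(counts)
    if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(counts)))
  }
  if (length(genes) != nrow(counts)) stopf("length(genes) != nrow(counts)")
  if (!is.data.frame(cell_meta) || nrow(cell_meta) != ncol(counts)) {
    stopf("cell_meta must be a data.frame with one row per cell")
  }
  if (is.null(cell_meta$time_h)) stopf("cell_meta must contain `time_h`")
  if (is.null(cell_meta$barcode)) {
    bc <- colnames(counts)
    if (is.null(bc)) bc <- paste0("cell", seq_len(ncol(counts)))
    cell_meta$barcode <- bc
  }
  if (is.null(cell_meta$cell_line)) cell_meta$cell_line <- "SIM"
  if (is.null(cell_meta$n_reads)) cell_meta$n_reads <- Matrix::colSums(counts)
  if (is.null(cell_meta$n_genes)) {
    cell_meta$n_genes <- Matrix::colSums(counts > 0)
  }
  rownames(counts) <- genes
  colnames(counts) <- cell_meta$barcode
  rownames(cell_meta) <- NULL
  structure(list(matrix = counts, genes = genes, cell_meta = cell_meta),
            class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  tp <- sort(unique(x$cell_meta$time_h))
  cat(sprintf("cell_counts: %d genes x %d cells\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  time points (h): %s\n", paste(tp, collapse = ", ")))
  cat(sprintf("  cell lines: %s\n",
              paste(unique(x$cell_meta$cell_line), collapse = ", ")))
  invisible(x)
}

#' @export
dim.cell_counts <- function(x) dim(x$matrix)

# subset cells by logical/integer index, keeping metadata aligned
subset_cells <- function(x, idx) {
  x$matrix <- x$matrix[, idx, drop = FALSE]
  x$cell_meta <- x$cell_meta[idx, , drop = FALSE]
  rownames(x$cell_meta) <- NULL
  x
}

subset_genes_cc <- function(x, idx) {
  x$matrix <- x$matrix[idx, , drop = FALSE]
  x$genes <- x$genes[idx]
  x
}

#' Write / read counts in MatrixMarket + TSV form
#'
#' Writes `matrix.mtx` (MatrixMarket), `genes.tsv` (one identifier per
#' line) and `metadata.tsv` (tab-separated cell metadata) into `dir`, the
#' on-disk dialect shared by the synthetic generator and the pipeline.
#'
#' @param x a [cell_counts()] object
#' @param dir output (input) directory; created if missing
#' @return `write_counts_mtx`: `dir`, invisibly. `read_counts_mtx`: a
#'   `cell_counts` object.
#' @export
write_counts_mtx <- function(x, dir) {
  stopifnot(inherits(x, "cell_counts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$matrix, file.path(dir, "matrix.mtx"))
  writeLines(x$genes, file.path(dir, "genes.tsv"))
  utils::write.table(x$cell_meta, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  meta <- utils::read.table(file.path(dir, "metadata.tsv"),
                            sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  cell_counts(m, meta, genes = genes)
}
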