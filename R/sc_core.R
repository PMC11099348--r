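#' Cell quality-control thresholds
#'
#' Inclusive ranges on per-cell unique reads and unique genes, and a
#' strict upper bound on percent mitochondrial reads. The defaults are
#' the Ishikawa-cell cutoffs: reads in \[8500, 35000\], genes in
#' \[2700, 6000\], mitochondrial percentage below 7.
#'
#' @param min_reads,max_reads inclusive unique-read range.
#' @param min_genes,max_genes inclusive unique-gene range.
#' @param max_mito_pct strict upper bound on percent mitochondrial reads.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_reads = 8500, max_reads = 35000,
                          min_genes = 2700, max_genes = 6000,
                          max_mito_pct = 7) {
  if (min_reads >= max_reads || min_genes >= max_genes) {
    stopf("min must be below max for read and gene ranges")
  }
  if (max_mito_pct < 0 || max_mito_pct > 100) {
    stopf("max_mito_pct must lie in [0, 100]")
  }
  structure(list(min_reads = min_reads, max_reads = max_reads,
                 min_genes = min_genes, max_genes = max_genes,
                 max_mito_pct = max_mito_pct),
            class = "qc_thresholds")
}

#' Filter cells on QC metadata
#'
#' Retains exactly the cells whose unique reads and unique genes fall
#' inside the inclusive threshold ranges and whose mitochondrial
#' percentage is strictly below the cutoff. Cell order is preserved and
#' the operation is idempotent.
#'
#' @param counts a [cell_counts()] object with `n_reads`, `n_genes` and
#'   `pct_mito` in its metadata.
#' @param thresholds a [qc_thresholds()].
#' @return the filtered `cell_counts`.
#' @export
filter_cells <- function(counts, thresholds = qc_thresholds()) {
  stopifnot(inherits(counts, "cell_counts"),
            inherits(thresholds, "qc_thresholds"))
  meta <- counts$cell_meta
  need <- c("n_reads", "n_genes", "pct_mito")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stopf("missing QC column(s): %s",
                          paste(miss, collapse = ", "))
  keep <- meta$n_reads >= thresholds$min_reads &
    meta$n_reads <= thresholds$max_reads &
    meta$n_genes >= thresholds$min_genes &
    meta$n_genes <= thresholds$max_genes &
    meta$pct_mito < thresholds$max_mito_pct
  subset_cells(counts, which(keep))
}

#' Filter genes on mean expression
#'
#' Keeps genes whose mean across all retained cells (all time points
#' pooled) exceeds `min_mean`. The inequality is strict by default: a
#' gene whose mean is exactly `min_mean` is removed.
#'
#' @param x a [cell_counts()] object or a numeric matrix (genes x cells,
#'   e.g. the log-normalized matrix).
#' @param min_mean expression-mean cutoff (default 0.01).
#' @param strict use `>` (default) rather than `>=`.
#' @return object of the same type with low-mean genes dropped. For a
#'   matrix input the retained row indices are available as
#'   `attr(, "kept")`.
#' @export
filter_genes <- function(x, min_mean = 0.01, strict = TRUE) {
  if (inherits(x, "cell_counts")) {
    if (ncol(x$matrix) < 1) stopf("no cells present")
    m <- Matrix::rowMeans(x$matrix)
    keep <- if (strict) m > min_mean else m >= min_mean
    return(subset_genes_cc(x, which(keep)))
  }
  if (ncol(x) < 1) stopf("no cells present")
  m <- Matrix::rowMeans(x)
  keep <- if (strict) m > min_mean else m >= min_mean
  out <- x[which(keep), , drop = FALSE]
  attr(out, "kept") <- which(keep)
  out
}

#' Log-normalize counts
#'
#' Per-cell library-size normalization followed by a natural-log
#' transform: `log(1 + scale * count / column_sum)`. Zeros map to zeros,
#' so the sparsity pattern is preserved, and scaling all counts of a cell
#' by a constant leaves its normalized column unchanged.
#'
#' @param counts a [cell_counts()] object or sparse/dense count matrix.
#' @param scale library-size scale factor (default 1e4).
#' @return sparse `dgCMatrix` of normalized values with the input
#'   dimnames.
#' @export
log_normalize <- function(counts, scale = 1e4) {
  m <- if (inherits(counts, "cell_counts")) counts$matrix else
    methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                            "generalMatrix"), "CsparseMatrix")
  tot <- Matrix::colSums(m)
  if (any(tot <= 0)) {
    stopf("%d cell(s) have zero total counts; remove them with QC first",
          sum(tot <= 0))
  }
  # operate on the non-zero entries of the CsparseMatrix directly
  j <- rep.int(seq_len(ncol(m)), diff(m@p))
  m@x <- log1p(scale * m@x / tot[j])
  m
}

#' Per-gene mean and coefficient of variation by group
#'
#' For each gene within each group of cells (a time point x cell line
#' stratum, say) computes the mean of the normalized expression and the
#' coefficient of variation CV = sample SD / mean (denominator n - 1).
#' CV is `NA` (undefined) where the mean is 0.
#'
#' @param normalized genes x cells matrix (dense or sparse) of
#'   log-normalized expression with rownames.
#' @param group factor/vector of length `ncol(normalized)`; statistics
#'   are computed within each level. Default: one group of all cells.
#' @return data.frame with `gene`, `group`, `mean`, `cv`.
#' @export
gene_stats <- function(normalized, group = NULL) {
  if (is.null(group)) group <- rep("all", ncol(normalized))
  if (length(group) != ncol(normalized)) {
    stopf("group must have one entry per cell")
  }
  genes <- rownames(normalized)
  if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(normalized)))
  out <- lapply(split(seq_along(group), group), function(idx) {
    if (length(idx) < 3) stopf("group with fewer than 3 cells")
    sub <- normalized[, idx, drop = FALSE]
    mu <- as.numeric(Matrix::rowMeans(sub))
    ex2 <- as.numeric(Matrix::rowMeans(sub^2))
    n <- length(idx)
    v <- pmax(ex2 - mu^2, 0) * n / (n - 1)
    cv <- ifelse(mu > 0, sqrt(v) / mu, NA_real_)
    data.frame(gene = genes, group = group[idx[1]], mean = mu, cv = cv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
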