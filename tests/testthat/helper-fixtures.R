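# Shared fixtures, all built in code.

# tiny count container with hand-set QC metadata
tiny_counts <- function(mat = matrix(c(0, 1, 2, 3, 4, 0), nrow = 2),
                        time_h = rep(0, ncol(mat)),
                        n_reads = NULL, n_genes = NULL, pct_mito = NULL) {
  meta <- data.frame(time_h = time_h)
  if (!is.null(n_reads)) meta$n_reads <- n_reads
  if (!is.null(n_genes)) meta$n_genes <- n_genes
  if (!is.null(pct_mito)) meta$pct_mito <- pct_mito
  cc <- cell_counts(mat, meta)
  if (is.null(pct_mito)) cc$cell_meta$pct_mito <- 0
  cc
}

# brute-force O(n*m) interval intersector used as the independent oracle
brute_overlap <- function(a, b) {
  out <- matrix(FALSE, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      out[i, j] <- a$chrom[i] == b$chrom[j] &&
        a$start[i] < b$end[j] && b$start[j] < a$end[i]
    }
  }
  out
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + sample.int(50, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# exhaustive rank-sum null: p from all choose(n+m, n) assignments of the
# observed pooled values (independent of the implementation's path)
enumerate_ranksum_p <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)])
  mu <- n * (length(pooled) + 1) / 2
  combos <- utils::combn(length(pooled), n)
  sums <- colSums(matrix(r[combos], nrow = n))
  mean(abs(sums - mu) >= abs(w_obs - mu) - 1e-9)
}
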