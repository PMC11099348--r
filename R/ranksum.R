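#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum test of two independent samples. For small samples (both
#' sizes at most `exact_max`) the p-value is computed by exhaustive
#' enumeration of all `choose(n + m, n)` assignments of the pooled ranks
#' (average ranks under ties), so it is exact even in the presence of
#' ties. Larger samples use the normal approximation with tie and
#' continuity correction, matching the conventional large-sample
#' rank-sum test.
#'
#' @param x,y numeric vectors.
#' @param exact_max exact-enumeration threshold on each group size
#'   (default 8).
#' @return list with `p_value`, `statistic` (rank sum of `x`) and
#'   `direction` (`sign(mean(x) - mean(y))`, 0 for identical means or a
#'   fully tied pool).
#' @export
rank_sum_test <- function(x, y, exact_max = 8L) {
  n <- length(x)
  m <- length(y)
  if (n < 1 || m < 1) stopf("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(n)])
  mu <- n * (n + m + 1) / 2

  if (length(unique(pooled)) == 1L) {
    return(list(p_value = 1, statistic = w, direction = 0))
  }

  if (n <= exact_max && m <= exact_max) {
    dev <- abs(w - mu)
    combos <- utils::combn(n + m, n)
    sums <- colSums(matrix(r[combos], nrow = n))
    p <- mean(abs(sums - mu) >= dev - 1e-9)
  } else {
    nties <- table(r)
    sigma2 <- (n * m / 12) *
      ((n + m + 1) - sum(nties^3 - nties) / ((n + m) * (n + m - 1)))
    z <- w - mu
    cc <- sign(z) * 0.5 # continuity correction toward the mean
    z <- (z - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  dm <- mean(x) - mean(y)
  list(p_value = p, statistic = w,
       direction = if (dm == 0) 0 else sign(dm))
}

#' Differential test of one gene at one time point
#'
#' Compares the single-cell expression distribution at `timepoint`
#' against the baseline time point with the two-sided rank-sum test of
#' [rank_sum_test()]. Direction is the sign of the mean shift relative
#' to baseline. No fold-change cutoff is involved at any stage.
#'
#' @param normalized genes x cells matrix with rownames.
#' @param gene gene identifier (rowname).
#' @param time_h numeric vector of per-cell time points.
#' @param timepoint treated time point to test.
#' @param baseline baseline time point (default 0).
#' @return list with `p_value`, `statistic`, `direction`.
#' @export
differential_test <- function(normalized, gene, time_h, timepoint,
                              baseline = 0) {
  i <- match(gene, rownames(normalized))
  if (is.na(i)) stopf("gene '%s' not found", gene)
  trt <- which(time_h == timepoint)
  ctl <- which(time_h == baseline)
  if (length(trt) < 3 || length(ctl) < 3) {
    stopf("both groups need at least 3 cells")
  }
  x <- as.numeric(normalized[i, trt])
  y <- as.numeric(normalized[i, ctl])
  rank_sum_test(x, y)
}

# All genes x all treated time points against baseline; returns a long
# data.frame(gene, timepoint, p_value, direction).
trajectory_tests <- function(normalized, time_h, baseline = 0,
                             timepoints = NULL) {
  if (is.null(timepoints)) {
    timepoints <- setdiff(sort(unique(time_h)), baseline)
  }
  genes <- rownames(normalized)
  ctl <- which(time_h == baseline)
  base_mat <- as.matrix(normalized[, ctl, drop = FALSE])
  res <- lapply(timepoints, function(tp) {
    trt <- which(time_h == tp)
    trt_mat <- as.matrix(normalized[, trt, drop = FALSE])
    p <- numeric(nrow(trt_mat))
    d <- numeric(nrow(trt_mat))
    for (i in seq_len(nrow(trt_mat))) {
      rs <- rank_sum_test(trt_mat[i, ], base_mat[i, ])
      p[i] <- rs$p_value
      d[i] <- rs$direction
    }
    data.frame(gene = genes, timepoint = tp, p_value = p, direction = d,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
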