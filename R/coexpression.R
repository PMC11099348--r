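# Single-cell co-expression of gene pairs defined by chromatin loops,
# trajectory groups or noise groups, against shuffled-pair nulls.

# canonical unordered pair key
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Derive gene pairs from loops
#'
#' Promoter-promoter (PP) pairs are genes whose promoters overlap the
#' two anchors of one filtered loop; shared-enhancer (SE) pairs are
#' genes whose loop-linked enhancer sets share at least one peak.
#' Self-pairs are dropped and unordered duplicates collapsed.
#'
#' @param promoters data.frame from [define_promoters()].
#' @param loops filtered loop table.
#' @param links per-gene enhancer sets from [link_enhancers()] (only
#'   needed for SE pairs; may be `NULL`).
#' @return list with data.frames `pp` and `se`, each with `gene_a`,
#'   `gene_b`, `provenance`.
#' @export
pairs_from_loops <- function(promoters, loops, links = NULL) {
  a1 <- data.frame(chrom = loops$chrom1, start = loops$start1,
                   end = loops$end1, stringsAsFactors = FALSE)
  a2 <- data.frame(chrom = loops$chrom2, start = loops$start2,
                   end = loops$end2, stringsAsFactors = FALSE)
  pp <- list()
  for (l in seq_len(nrow(loops))) {
    g1 <- promoters$gene[promoters$chrom == a1$chrom[l] &
                           promoters$start < a1$end[l] &
                           a1$start[l] < promoters$end]
    g2 <- promoters$gene[promoters$chrom == a2$chrom[l] &
                           promoters$start < a2$end[l] &
                           a2$start[l] < promoters$end]
    if (length(g1) && length(g2)) {
      grid <- expand.grid(gene_a = g1, gene_b = g2,
                          stringsAsFactors = FALSE)
      pp[[length(pp) + 1L]] <- grid[grid$gene_a != grid$gene_b, ]
    }
  }
  pp <- if (length(pp)) do.call(rbind, pp) else
    data.frame(gene_a = character(), gene_b = character())
  pp <- pp[!duplicated(pair_key(pp$gene_a, pp$gene_b)), , drop = FALSE]
  if (nrow(pp)) pp$provenance <- "promoter-promoter loop"

  se <- data.frame(gene_a = character(), gene_b = character())
  if (!is.null(links)) {
    peak2gene <- list()
    for (g in names(links)) {
      for (pid in links[[g]]$peak_id) {
        peak2gene[[pid]] <- c(peak2gene[[pid]], g)
      }
    }
    rows <- list()
    for (gs in peak2gene) {
      gs <- unique(gs)
      if (length(gs) >= 2) {
        cmb <- utils::combn(sort(gs), 2)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_a = cmb[1, ], gene_b = cmb[2, ], stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) {
      se <- do.call(rbind, rows)
      se <- se[!duplicated(pair_key(se$gene_a, se$gene_b)), , drop = FALSE]
      se$provenance <- "shared enhancer"
    }
  }
  rownames(pp) <- rownames(se) <- NULL
  list(pp = pp, se = se)
}

#' Pairwise Spearman correlation across cells
#'
#' Spearman rank correlation (average ranks under ties) of each gene
#' pair over a cell subset. Pairs containing a zero-variance gene are
#' flagged with `NA`.
#'
#' @param normalized genes x cells matrix with rownames.
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @param cells optional column index/logical subset (default all).
#' @return the pairs with an added `rho` column.
#' @export
pairwise_spearman <- function(normalized, pairs, cells = NULL) {
  if (is.null(cells)) cells <- seq_len(ncol(normalized))
  if (length(seq_len(ncol(normalized))[cells]) < 10) {
    stopf("need at least 10 cells")
  }
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  miss <- setdiff(genes, rownames(normalized))
  if (length(miss)) stopf("gene(s) absent from matrix: %s",
                          paste(utils::head(miss, 3), collapse = ", "))
  sub <- as.matrix(normalized[genes, cells, drop = FALSE])
  ranks <- t(apply(sub, 1, rank))
  ctr <- ranks - rowMeans(ranks)
  ss <- sqrt(rowSums(ctr^2))
  ia <- match(pairs$gene_a, genes)
  ib <- match(pairs$gene_b, genes)
  num <- rowSums(ctr[ia, , drop = FALSE] * ctr[ib, , drop = FALSE])
  den <- ss[ia] * ss[ib]
  pairs$rho <- ifelse(den > 0, num / den, NA_real_)
  pairs
}

#' Shuffled control pairs
#'
#' Reshuffles the partner column of a pair list into a derangement-style
#' control set of the same size: no output pair reproduces an input pair
#' (unordered) and no self-pairs are created. Sampling is retried up to
#' `max_tries` times before failing, which only happens for tiny pair
#' sets with no valid reshuffle.
#'
#' @param pairs data.frame with `gene_a`, `gene_b` (>= 2 pairs).
#' @param seed integer seed.
#' @param max_tries rejection-sampling retries (default 100).
#' @return data.frame of control pairs with `provenance = "shuffled"`.
#' @export
shuffle_pairs <- function(pairs, seed = 1L, max_tries = 100) {
  n <- nrow(pairs)
  if (n < 2) stopf("need at least 2 pairs to shuffle")
  orig <- pair_key(pairs$gene_a, pairs$gene_b)
  with_seed(op_seed(seed, 6L), {
    for (t in seq_len(max_tries)) {
      perm <- sample.int(n)
      b <- pairs$gene_b[perm]
      key <- pair_key(pairs$gene_a, b)
      if (!any(key %in% orig) && !any(pairs$gene_a == b)) {
        return(data.frame(gene_a = pairs$gene_a, gene_b = b,
                          provenance = "shuffled",
                          stringsAsFactors = FALSE))
      }
    }
    stopf("no valid derangement found in %d tries", max_tries)
  })
}

#' Compare two correlation distributions
#'
#' Two-sided Wilcoxon rank-sum test of observed versus control pair
#' correlations with Bonferroni adjustment for `n_comparisons` parallel
#' comparisons (`p_adj = min(1, p * n_comparisons)`).
#'
#' @param rho_obs,rho_null numeric vectors of pair correlations
#'   (`NA` dropped; both need >= 3 values).
#' @param n_comparisons Bonferroni divisor (default 1).
#' @return list with `statistic` (W), `p_value`, `p_adjusted`.
#' @export
compare_pair_sets <- function(rho_obs, rho_null, n_comparisons = 1) {
  rho_obs <- rho_obs[is.finite(rho_obs)]
  rho_null <- rho_null[is.finite(rho_null)]
  if (length(rho_obs) < 3 || length(rho_null) < 3) {
    stopf("both sets need at least 3 defined correlations")
  }
  wt <- stats::wilcox.test(rho_obs, rho_null, alternative = "two.sided",
                           exact = FALSE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       p_adjusted = min(1, wt$p.value * n_comparisons))
}

#' Composition of correlation quantiles by noise label
#'
#' Bins pair correlations into equal-occupancy quantile bins and
#' reports, per bin, the proportion of pairs carrying each label
#' (e.g. high-high versus low-low noise pairs). Rows sum to 1.
#'
#' @param rho numeric vector of pair correlations.
#' @param labels per-pair labels.
#' @param n_quantiles number of quantile bins (default 5).
#' @return data.frame with `quantile`, `n` and one proportion column per
#'   label.
#' @export
correlation_quantile_composition <- function(rho, labels, n_quantiles = 5) {
  stopifnot(length(rho) == length(labels))
  ok <- is.finite(rho)
  rho <- rho[ok]
  labels <- labels[ok]
  bin <- occupancy_bins(rho, n_quantiles)
  labs <- sort(unique(labels))
  out <- data.frame(quantile = seq_len(n_quantiles),
                    n = tabulate(bin, n_quantiles))
  if (any(out$n == 0)) warning("empty quantile bin(s)")
  for (l in labs) {
    out[[l]] <- vapply(seq_len(n_quantiles), function(b) {
      nb <- sum(bin == b)
      if (nb == 0) NA_real_ else sum(labels == l & bin == b) / nb
    }, numeric(1))
  }
  out
}

#' Within-group pairwise correlation per time point
#'
#' For each trajectory group, computes the Spearman correlation of all
#' unordered within-group gene pairs separately at each time point.
#' Groups of fewer than 2 genes are skipped.
#'
#' @param normalized genes x cells matrix with rownames.
#' @param time_h per-cell time points.
#' @param groups named per-gene group labels (e.g. trajectory calls,
#'   with controls relabeled `"Control"`).
#' @param max_pairs optional cap on pairs per group (uniformly sampled,
#'   seeded) to bound the computation on large groups.
#' @param seed seed used only when `max_pairs` truncates.
#' @return data.frame `group`, `timepoint`, `gene_a`, `gene_b`, `rho`.
#' @export
trajectory_group_correlation <- function(normalized, time_h, groups,
                                         max_pairs = Inf, seed = 1L) {
  tps <- sort(unique(time_h))
  out <- list()
  for (g in unique(groups)) {
    gs <- intersect(names(groups)[groups == g], rownames(normalized))
    if (length(gs) < 2) next
    cmb <- utils::combn(gs, 2)
    if (ncol(cmb) > max_pairs) {
      cmb <- with_seed(op_seed(seed, 7L),
                       cmb[, sample.int(ncol(cmb), max_pairs), drop = FALSE])
    }
    pairs <- data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                        stringsAsFactors = FALSE)
    for (tp in tps) {
      res <- pairwise_spearman(normalized, pairs,
                               cells = which(time_h == tp))
      res$group <- g
      res$timepoint <- tp
      out[[length(out) + 1L]] <- res
    }
  }
  if (!length(out)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      rho = numeric(), group = character(),
                      timepoint = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("group", "timepoint", "gene_a", "gene_b", "rho")]
}
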