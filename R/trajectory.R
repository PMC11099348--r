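#' Classify genes into temporal response trajectories
#'
#' Runs per-gene rank-sum tests of every treated time point against the
#' baseline, adjusts p-values across genes within each time-point
#' contrast, and assigns each gene exactly one label:
#' * **EarlyUp / EarlyDown** — significant change at the first treated
#'   time point (2 h), direction by the sign of the mean shift there.
#'   Early takes precedence even when later time points are also
#'   significant.
#' * **LateUp / LateDown** — not significant at 2 h but significant at
#'   4 or 8 h; direction at the earliest significant late time point.
#' * **NotRegulated** — no significant time point.
#'
#' There is no fold-change cutoff: significance alone drives the calls.
#'
#' @param normalized genes x cells log-normalized matrix with rownames.
#' @param time_h per-cell time points (hours).
#' @param baseline baseline time point (default 0).
#' @param alpha significance level after correction (default 0.05).
#' @param correction one of `"bonferroni"`, `"BH"`, `"none"` — applied
#'   across genes within each time point.
#' @param tests optional precomputed long test table (as produced
#'   internally: `gene`, `timepoint`, `p_value`, `direction`); when
#'   supplied, `normalized`/`time_h` are ignored.
#' @return data.frame of class `trajectory_calls`: one row per gene with
#'   `label` and per-time-point `p_<t>`, `padj_<t>`, `dir_<t>` columns.
#' @export
classify_trajectories <- function(normalized = NULL, time_h = NULL,
                                  baseline = 0, alpha = 0.05,
                                  correction = c("bonferroni", "BH", "none"),
                                  tests = NULL) {
  correction <- match.arg(correction)
  if (is.null(tests)) {
    tests <- trajectory_tests(normalized, time_h, baseline)
  }
  need <- c("gene", "timepoint", "p_value", "direction")
  stopifnot(all(need %in% names(tests)))
  tps <- sort(unique(tests$timepoint))
  if (length(tps) < 1) stopf("no treated time points in tests")

  genes <- unique(tests$gene)
  wide_p <- wide_padj <- wide_dir <-
    matrix(NA_real_, length(genes), length(tps),
           dimnames = list(genes, as.character(tps)))
  for (k in seq_along(tps)) {
    sub <- tests[tests$timepoint == tps[k], ]
    if (!setequal(sub$gene, genes)) {
      stopf("missing tests for time point %s", tps[k])
    }
    i <- match(sub$gene, genes)
    wide_p[i, k] <- sub$p_value
    wide_padj[i, k] <- stats::p.adjust(
      sub$p_value, method = if (correction == "none") "none" else correction)
    wide_dir[i, k] <- sub$direction
  }

  early_tp <- 1L # first treated time point defines "Early"
  label <- character(length(genes))
  for (g in seq_along(genes)) {
    sig <- wide_padj[g, ] < alpha
    if (sig[early_tp]) {
      d <- wide_dir[g, early_tp]
      label[g] <- if (d >= 0) "EarlyUp" else "EarlyDown"
    } else if (any(sig[-early_tp])) {
      first <- setdiff(which(sig), early_tp)[1]
      d <- wide_dir[g, first]
      label[g] <- if (d >= 0) "LateUp" else "LateDown"
    } else {
      label[g] <- "NotRegulated"
    }
  }

  out <- data.frame(gene = genes, label = label, stringsAsFactors = FALSE)
  for (k in seq_along(tps)) {
    out[[paste0("p_", tps[k])]] <- wide_p[, k]
    out[[paste0("padj_", tps[k])]] <- wide_padj[, k]
    out[[paste0("dir_", tps[k])]] <- wide_dir[, k]
  }
  class(out) <- c("trajectory_calls", "data.frame")
  out
}

#' @export
print.trajectory_calls <- function(x, ...) {
  cat("trajectory_calls:", nrow(x), "genes\n")
  print(table(x$label))
  invisible(as.data.frame(x))
}

#' Mean-expression level classes
#'
#' Rank-based split of genes into Low (bottom 20%), Medium (middle 60%)
#' and High (top 20%) mean-expression classes. Ties are broken by stable
#' gene order, so class sizes are always `floor`-exact.
#'
#' @param means named numeric vector of per-gene means (names = gene
#'   ids), or unnamed with `genes` supplied.
#' @param genes optional gene identifiers.
#' @param tail_frac tail fraction for Low and High (default 0.2).
#' @return data.frame with `gene`, `mean`, `class` in input order.
#' @export
classify_mean_levels <- function(means, genes = NULL, tail_frac = 0.2) {
  if (is.null(genes)) genes <- names(means)
  if (is.null(genes)) genes <- paste0("gene", seq_along(means))
  n <- length(means)
  if (n < 5) stopf("need at least 5 genes")
  ord <- order(means, seq_len(n))
  n_low <- floor(tail_frac * n)
  n_high <- floor(tail_frac * n)
  cls <- rep("Medium", n)
  cls[ord[seq_len(n_low)]] <- "Low"
  cls[ord[(n - n_high + 1):n]] <- "High"
  data.frame(gene = genes, mean = means, class = cls,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Stratified sampling of mean-matched control genes
#'
#' Draws unregulated control genes whose mean-expression distribution
#' mirrors that of the regulated genes: means are cut into
#' equal-occupancy bins, and controls are sampled from the NotRegulated
#' pool of each bin in proportion to the regulated genes' occupancy of
#' that bin.
#'
#' @param calls a [classify_trajectories()] result (or data.frame with
#'   `gene`, `label`).
#' @param means named per-gene mean vector covering all called genes.
#' @param n_controls number of controls to draw.
#' @param n_bins number of equal-occupancy mean bins (default 10).
#' @param seed integer seed.
#' @return character vector of control gene ids.
#' @export
sample_control_genes <- function(calls, means, n_controls, n_bins = 10,
                                 seed = 1L) {
  stopifnot(all(c("gene", "label") %in% names(calls)))
  mu <- means[calls$gene]
  if (anyNA(mu)) stopf("means missing for some called genes")
  bin <- occupancy_bins(mu, n_bins)
  reg <- calls$label != "NotRegulated"
  if (!any(reg)) stopf("no regulated genes to mirror")
  occ <- tabulate(bin[reg], n_bins)
  want <- floor(n_controls * occ / sum(occ))
  # distribute the rounding remainder over the fullest bins
  rem <- n_controls - sum(want)
  if (rem > 0) {
    extra <- order(occ, decreasing = TRUE)[seq_len(rem)]
    want[extra] <- want[extra] + 1L
  }
  with_seed(op_seed(seed, 4L), {
    out <- character(0)
    for (b in seq_len(n_bins)) {
      if (want[b] == 0L) next
      pool <- calls$gene[!reg & bin == b]
      if (length(pool) < want[b]) {
        stopf("mean bin %d has %d eligible control genes but %d are needed",
              b, length(pool), want[b])
      }
      out <- c(out, pool[sample.int(length(pool), want[b])])
    }
    out
  })
}
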