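# Interval conventions throughout: BED-style 0-based half-open
# [start, end) coordinates; two intervals overlap iff they share a
# chromosome and a.start < b.end and b.start < a.end.

#' Half-open interval overlap
#'
#' @param a,b data.frames with `chrom`, `start`, `end` (recycled against
#'   each other elementwise).
#' @return logical vector.
#' @export
interval_overlap <- function(a, b) {
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

# indices of rows in `query` overlapping ANY row of `subject`
overlaps_any <- function(query, subject) {
  if (nrow(subject) == 0 || nrow(query) == 0) {
    return(rep(FALSE, nrow(query)))
  }
  out <- logical(nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    sj <- subject[subject$chrom == ch, , drop = FALSE]
    if (nrow(sj) == 0) next
    out[qi] <- vapply(qi, function(i) {
      any(query$start[i] < sj$end & sj$start < query$end[i])
    }, logical(1))
  }
  out
}

#' Filter chromatin loops
#'
#' Retains loops with at least `min_reads` supporting reads AND an FDR
#' strictly below `fdr_cutoff` (loops with fewer than 3 reads or
#' FDR >= 0.05 are removed under the defaults). Idempotent.
#'
#' @param loops data.frame with `reads` and `fdr` columns.
#' @param min_reads minimum read support (default 3).
#' @param fdr_cutoff strict FDR bound (default 0.05).
#' @return the retained loops.
#' @export
filter_loops <- function(loops, min_reads = 3, fdr_cutoff = 0.05) {
  stopifnot(all(c("reads", "fdr") %in% names(loops)))
  if (any(loops$reads < 0)) stopf("negative read counts in loops")
  if (any(loops$fdr < 0 | loops$fdr > 1)) stopf("fdr must lie in [0, 1]")
  loops[loops$reads >= min_reads & loops$fdr < fdr_cutoff, , drop = FALSE]
}

#' Define promoter windows around the TSS
#'
#' A promoter is a `width`-bp window centered on the transcription start
#' site, clamped at coordinate 0. The TSS is taken from a `tss` column
#' when present; otherwise from transcript endpoints, using the strand to
#' pick the correct side (`tx_start` for `+`, `tx_end` for `-`).
#'
#' @param tss_table data.frame with `gene`, `chrom` and either `tss` or
#'   `tx_start`/`tx_end` plus `strand`.
#' @param width promoter width in bp (default 500).
#' @return data.frame `gene`, `chrom`, `start`, `end`.
#' @export
define_promoters <- function(tss_table, width = 500) {
  stopifnot(all(c("gene", "chrom") %in% names(tss_table)))
  if (!is.null(tss_table$tss)) {
    tss <- tss_table$tss
  } else {
    if (is.null(tss_table$strand)) {
      stopf("strand required to derive the TSS from transcript endpoints")
    }
    stopifnot(all(c("tx_start", "tx_end") %in% names(tss_table)))
    tss <- ifelse(tss_table$strand == "-", tss_table$tx_end,
                  tss_table$tx_start)
  }
  half <- width %/% 2
  data.frame(gene = tss_table$gene, chrom = tss_table$chrom,
             start = pmax(tss - half, 0), end = tss + half,
             stringsAsFactors = FALSE)
}

#' Link enhancers to genes through loops
#'
#' An enhancer of a gene is a peak (H3K27ac-style) overlapping the
#' distal anchor of a filtered loop whose other anchor overlaps the
#' gene's promoter window. Both anchors are checked against the
#' promoter; peaks on the promoter-side anchor that themselves overlap
#' the promoter are excluded; peaks reached through several loops are
#' counted once.
#'
#' @param promoters data.frame from [define_promoters()].
#' @param loops filtered loop table (`chrom1,start1,end1,chrom2,start2,
#'   end2`, see [filter_loops()]).
#' @param peaks data.frame with `chrom`, `start`, `end` and optionally
#'   `peak_id`.
#' @return named list (per gene) of data.frames of linked peaks;
#'   attribute `"n_enhancers"` holds the per-gene counts.
#' @export
link_enhancers <- function(promoters, loops, peaks) {
  if (is.null(peaks$peak_id)) {
    peaks$peak_id <- sprintf("peak%06d", seq_len(nrow(peaks)))
  }
  a1 <- data.frame(chrom = loops$chrom1, start = loops$start1,
                   end = loops$end1, stringsAsFactors = FALSE)
  a2 <- data.frame(chrom = loops$chrom2, start = loops$start2,
                   end = loops$end2, stringsAsFactors = FALSE)
  out <- vector("list", nrow(promoters))
  names(out) <- promoters$gene
  for (g in seq_len(nrow(promoters))) {
    pr <- promoters[g, , drop = FALSE]
    hit1 <- pr$chrom == a1$chrom & pr$start < a1$end & a1$start < pr$end
    hit2 <- pr$chrom == a2$chrom & pr$start < a2$end & a2$start < pr$end
    distal <- rbind(a2[hit1, , drop = FALSE], a1[hit2, , drop = FALSE])
    if (nrow(distal) == 0) {
      out[[g]] <- peaks[0, , drop = FALSE]
      next
    }
    in_distal <- overlaps_any(peaks, distal)
    on_promoter <- pr$chrom == peaks$chrom & pr$start < peaks$end &
      peaks$start < pr$end
    sel <- peaks[in_distal & !on_promoter, , drop = FALSE]
    out[[g]] <- sel[!duplicated(sel$peak_id), , drop = FALSE]
  }
  attr(out, "n_enhancers") <- vapply(out, nrow, integer(1))
  out
}

#' Integrated signal over intervals
#'
#' Counts the reads (weight-1 BED intervals) overlapping each query
#' interval, any-overlap rule, half-open coordinates. Reads on
#' chromosomes absent from the coverage source contribute 0 (with a
#' warning for query chromosomes never seen).
#'
#' @param intervals data.frame with `chrom`, `start`, `end`.
#' @param reads data.frame of read intervals (`chrom`, `start`, `end`).
#' @return integer vector of per-interval read counts.
#' @export
quantify_signal <- function(intervals, reads) {
  n <- nrow(intervals)
  out <- integer(n)
  seen <- unique(reads$chrom)
  missing_ch <- setdiff(unique(intervals$chrom), seen)
  if (length(missing_ch)) {
    warning("no coverage on chromosome(s): ",
            paste(missing_ch, collapse = ", "))
  }
  for (ch in intersect(unique(intervals$chrom), seen)) {
    qi <- which(intervals$chrom == ch)
    r <- reads[reads$chrom == ch, , drop = FALSE]
    s <- sort(r$start)
    e <- sort(r$end)
    nr <- nrow(r)
    # reads overlapping [a, b) = nr - #(start >= b) - #(end <= a)
    out[qi] <- nr -
      (nr - findInterval(intervals$end[qi] - 1L, s)) -
      findInterval(intervals$start[qi], e)
  }
  out
}

#' Column-wise Z-scores of a gene-by-feature signal matrix
#'
#' Standardizes each feature across genes to mean 0, sample SD 1.
#' Zero-variance features become all-zero columns with a warning.
#'
#' @param mat numeric matrix (genes x features).
#' @return matrix of the same shape.
#' @export
zscore_features <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stopf("need >= 2 genes to Z-score")
  mu <- colMeans(mat)
  sd <- apply(mat, 2, stats::sd)
  zero <- sd == 0 | !is.finite(sd)
  if (any(zero)) {
    warning("zero-variance feature(s) set to 0: ",
            paste(colnames(mat)[zero], collapse = ", "))
    sd[zero] <- 1
    mu[zero] <- mat[1, zero]
  }
  sweep(sweep(mat, 2, mu), 2, sd, "/")
}

#' Aggregate enhancer score
#'
#' `sum(log2(s + 1))` over a gene's enhancers, where `s` is the
#' per-enhancer Z-score of integrated signal. Because Z-scores below -1
#' make the logarithm undefined, the argument is floored at
#' `epsilon = 2^-10` (preserving order while bounding the penalty); set
#' `drop_low = TRUE` to instead drop such enhancers from the sum. The
#' empty repertoire scores 0.
#'
#' @param s numeric vector of per-enhancer Z-scores.
#' @param epsilon floor on `s + 1` (default `2^-10`).
#' @param drop_low drop enhancers with `s <= -1` instead of clamping.
#' @return scalar score.
#' @export
enhancer_score <- function(s, epsilon = 2^-10, drop_low = FALSE) {
  if (length(s) == 0) return(0)
  if (drop_low) s <- s[s > -1]
  if (length(s) == 0) return(0)
  sum(log2(pmax(s + 1, epsilon)))
}

#' Count ER-bound enhancers
#'
#' Number of a gene's enhancers overlapping at least one ER ChIP-seq
#' peak; an enhancer overlapping several peaks counts once.
#'
#' @param enhancers data.frame with `chrom`, `start`, `end`.
#' @param er_peaks data.frame of ER peak intervals.
#' @return integer count.
#' @export
count_erbs <- function(enhancers, er_peaks) {
  sum(overlaps_any(enhancers, er_peaks))
}

#' Gene length from transcript annotations
#'
#' `end - start` of each gene's transcript; genes with several
#' transcripts get the longest.
#'
#' @param transcripts data.frame with `gene`, `tx_start`, `tx_end`.
#' @return named numeric vector of lengths (bp).
#' @export
gene_length <- function(transcripts) {
  stopifnot(all(c("gene", "tx_start", "tx_end") %in% names(transcripts)))
  len <- transcripts$tx_end - transcripts$tx_start
  if (any(len <= 0)) stopf("zero- or negative-length transcript record")
  out <- tapply(len, transcripts$gene, max)
  stats::setNames(as.numeric(out), names(out))
}

#' Build per-gene regulatory feature profiles
#'
#' End-to-end feature engineering over a simulated or real landscape:
#' filters loops, defines 500-bp promoters, links enhancers through the
#' loops, Z-scores promoter and enhancer signals per feature across
#' genes, and assembles the gene x feature design matrix used by the
#' ranking module — per-feature promoter Z-scores (`<feature>_promoter`),
#' per-feature enhancer scores (`<feature>_enhancer_score` =
#' sum log2(Z+1) over the gene's enhancers), `n_enhancers`, `n_erbs`,
#' and `gene_length`.
#'
#' @param tss_table TSS/transcript table (see [define_promoters()]).
#' @param promoter_signal gene x feature matrix of raw promoter signal.
#' @param enhancers peak table with `peak_id`.
#' @param enhancer_signal peak x feature matrix of raw enhancer signal.
#' @param loops raw loop table (filtered internally).
#' @param er_peaks ER peak intervals.
#' @param promoter_width promoter window width (default 500).
#' @return list of class `reg_profiles`: `features` (the design matrix),
#'   `links` (per-gene enhancer sets), `promoters`, `loops` (filtered),
#'   and `provenance` (feature -> promoter/enhancer/count).
#' @export
build_regulatory_profiles <- function(tss_table, promoter_signal,
                                      enhancers, enhancer_signal,
                                      loops, er_peaks,
                                      promoter_width = 500) {
  loops <- filter_loops(loops)
  promoters <- define_promoters(tss_table, width = promoter_width)
  links <- link_enhancers(promoters, loops,
                          enhancers[, c("chrom", "start", "end", "peak_id")])
  genes <- promoters$gene

  prom_z <- zscore_features(promoter_signal[genes, , drop = FALSE])
  colnames(prom_z) <- paste0(colnames(promoter_signal), "_promoter")

  enh_z <- if (nrow(enhancer_signal) >= 2) {
    zscore_features(enhancer_signal)
  } else {
    enhancer_signal
  }
  scores <- sapply(colnames(enh_z), function(f) {
    vapply(genes, function(g) {
      ids <- links[[g]]$peak_id
      enhancer_score(enh_z[ids, f])
    }, numeric(1))
  })
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = length(genes))
  colnames(scores) <- paste0(colnames(enh_z), "_enhancer_score")

  n_enh <- attr(links, "n_enhancers")
  n_erbs <- vapply(genes, function(g) count_erbs(links[[g]], er_peaks),
                   integer(1))
  glen <- gene_length(tss_table)[genes]

  feats <- cbind(prom_z, scores, n_enhancers = n_enh,
                 n_erbs = n_erbs, gene_length = as.numeric(glen))
  rownames(feats) <- genes
  provenance <- c(rep("promoter", ncol(prom_z)),
                  rep("enhancer", ncol(scores)),
                  rep("count", 3))
  names(provenance) <- colnames(feats)
  structure(list(features = feats, links = links, promoters = promoters,
                 loops = loops, provenance = provenance),
            class = "reg_profiles")
}

#' @export
print.reg_profiles <- function(x, ...) {
  cat(sprintf("reg_profiles: %d genes x %d features (%d promoter, %d enhancer, %d count)\n",
              nrow(x$features), ncol(x$features),
              sum(x$provenance == "promoter"),
              sum(x$provenance == "enhancer"),
              sum(x$provenance == "count")))
  invisible(x)
}
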