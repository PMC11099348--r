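#' Simulate a cis-regulatory landscape tied to planted gene labels
#'
#' Builds a synthetic genome (single chromosome `chrS`, genes spaced
#' 100 kb apart, 0-based half-open intervals) and emits every regulatory
#' input the downstream feature modules consume: a TSS table, per-feature
#' promoter signals, H3K27ac-style enhancer peaks, loops (with read count
#' and FDR columns) connecting promoters to their enhancers, and ER peak
#' calls. Features listed in `informative_features` differ by
#' `assoc_strength` standard deviations between genes carrying the
#' feature's target label and all other genes; the remaining features are
#' label-independent N(0,1) noise. Genes planted EarlyUp stochastically
#' receive more enhancers and a higher chance of ER overlap at each
#' enhancer, mirroring the association of multiple ER-bound enhancers
#' with fast activation.
#'
#' @param truth per-gene truth data.frame from [simulate_counts()] (needs
#'   `gene` and `trajectory`), or any data.frame with those columns.
#' @param feature_names feature identifiers; names ending in
#'   `"_promoter"` are promoter features, in `"_enhancer"` enhancer
#'   features (both signal types are emitted for other names).
#' @param informative_features subset of `feature_names` made predictive;
#'   each is cycled through the non-Null labels as its target group.
#'   Default: the first half of `feature_names`.
#' @param assoc_strength group-mean shift in SD units (0 = null
#'   landscape).
#' @param enhancer_rate_base,enhancer_rate_earlyup Poisson means of the
#'   per-gene enhancer count.
#' @param erbs_prob_base,erbs_prob_earlyup probability that an enhancer
#'   overlaps an ER peak.
#' @param seed integer seed.
#' @return A list of class `sim_landscape`: `tss` (gene, chrom, tss,
#'   strand, tx_start, tx_end), `promoter_signal` (gene x feature matrix),
#'   `enhancers` (BED-like data.frame with `peak_id`),
#'   `enhancer_signal` (peak x feature matrix), `loops` (8-column
#'   chrom1,start1,end1,chrom2,start2,end2,reads,fdr), `er_peaks`
#'   (BED-like), `feature_targets` (feature -> target label or NA), and
#'   the updated `truth` with `n_enhancers_planted`.
#' @export
simulate_regulatory_landscape <- function(truth,
                                          feature_names,
                                          informative_features = NULL,
                                          assoc_strength = 2,
                                          enhancer_rate_base = 2,
                                          enhancer_rate_earlyup = 4,
                                          erbs_prob_base = 0.3,
                                          erbs_prob_earlyup = 0.8,
                                          seed = 1L) {
  stopifnot(is.data.frame(truth), all(c("gene", "trajectory") %in% names(truth)))
  if (anyDuplicated(truth$gene)) stopf("duplicate gene ids in truth")
  if (is.null(informative_features)) {
    informative_features <- feature_names[seq_len(length(feature_names) %/% 2)]
  }
  bad <- setdiff(informative_features, feature_names)
  if (length(bad)) stopf("unknown feature name(s): %s",
                         paste(bad, collapse = ", "))
  if (assoc_strength < 0) stopf("assoc_strength must be >= 0")

  with_seed(op_seed(seed, 1L), {
    ng <- nrow(truth)
    genes <- truth$gene
    labels <- truth$trajectory
    lab_levels <- c("EarlyUp", "EarlyDown", "LateUp", "LateDown")

    # geometry: gene i occupies a 10 kb transcript inside its 100 kb slot
    strand <- rep(c("+", "-"), length.out = ng)
    slot0 <- (seq_len(ng) - 1L) * 100000L
    tx_start <- slot0 + 45000L
    tx_end <- tx_start + 10000L
    tss <- ifelse(strand == "+", tx_start, tx_end)
    tss_tab <- data.frame(gene = genes, chrom = "chrS", tss = tss,
                          strand = strand, tx_start = tx_start,
                          tx_end = tx_end, stringsAsFactors = FALSE)

    targets <- stats::setNames(rep(NA_character_, length(feature_names)),
                               feature_names)
    present <- lab_levels[lab_levels %in% labels]
    if (length(present) && length(informative_features)) {
      targets[informative_features] <-
        rep(present, length.out = length(informative_features))
    }

    shift_for <- function(feat) {
      tgt <- targets[[feat]]
      if (is.na(tgt) || assoc_strength == 0) return(numeric(ng))
      ifelse(labels == tgt, assoc_strength, 0)
    }

    promoter_signal <- vapply(feature_names, function(f) {
      stats::rnorm(ng) + shift_for(f)
    }, numeric(ng))
    rownames(promoter_signal) <- genes

    # enhancer counts: EarlyUp genes draw from a higher Poisson rate
    lambda <- ifelse(labels == "EarlyUp",
                     enhancer_rate_earlyup, enhancer_rate_base)
    n_enh <- stats::rpois(ng, lambda)

    # offsets within +/- 50 kb of the TSS, clear of the 500 bp promoter;
    # drawn without replacement within each gene
    gi <- rep.int(seq_len(ng), n_enh)
    off <- unlist(lapply(n_enh[n_enh > 0L], function(k)
      sample(c(-(2:50), 2:50), k))) * 1000L
    K <- length(gi)
    e_start <- pmax(tss[gi] + off, 0L)
    e_end <- e_start + 500L
    enhancers <- data.frame(
      chrom = rep("chrS", K), start = e_start, end = e_end,
      peak_id = sprintf("peak%06d", seq_len(K)), gene = genes[gi],
      stringsAsFactors = FALSE)
    p_er <- ifelse(labels[gi] == "EarlyUp", erbs_prob_earlyup,
                   erbs_prob_base)
    has_er <- stats::runif(K) < p_er
    er_peaks <- data.frame(chrom = rep("chrS", sum(has_er)),
                           start = e_start[has_er] + 100L,
                           end = e_start[has_er] + 400L,
                           stringsAsFactors = FALSE)
    # one loop per enhancer: promoter-side anchor 1 kb around the TSS,
    # distal anchor 1 kb around the enhancer
    loop_tab <- data.frame(
      chrom1 = rep("chrS", K), start1 = pmax(tss[gi] - 500L, 0L),
      end1 = tss[gi] + 500L,
      chrom2 = rep("chrS", K), start2 = pmax(e_start - 250L, 0L),
      end2 = e_end + 250L,
      reads = 3L + stats::rpois(K, 10),
      fdr = stats::runif(K, 0, 0.049),
      stringsAsFactors = FALSE)

    # a few sub-threshold decoy loops in intergenic space; the loop
    # filter must remove every one of them
    if (ng >= 2) {
      n_decoy <- max(2L, ng %/% 50L)
      pos <- sort(sample.int(ng * 100000L - 30000L, n_decoy))
      decoys <- data.frame(
        chrom1 = "chrS", start1 = pos, end1 = pos + 1000L,
        chrom2 = "chrS", start2 = pos + 20000L, end2 = pos + 21000L,
        reads = rep(c(0L, 2L), length.out = n_decoy),
        fdr = rep(c(0.01, 0.5), length.out = n_decoy),
        stringsAsFactors = FALSE)
      decoys$reads[decoys$fdr >= 0.05] <- 50L
      loop_tab <- rbind(loop_tab, decoys)
    }

    n_peaks <- nrow(enhancers)
    enhancer_signal <- vapply(feature_names, function(f) {
      s <- stats::rnorm(n_peaks)
      if (n_peaks) s <- s + shift_for(f)[match(enhancers$gene, genes)]
      s
    }, numeric(n_peaks))
    if (n_peaks) rownames(enhancer_signal) <- enhancers$peak_id

    truth$n_enhancers_planted <- n_enh
    structure(list(tss = tss_tab,
                   promoter_signal = promoter_signal,
                   enhancers = enhancers,
                   enhancer_signal = enhancer_signal,
                   loops = loop_tab,
                   er_peaks = er_peaks,
                   feature_targets = targets,
                   truth = truth),
              class = "sim_landscape")
  })
}

#' @export
print.sim_landscape <- function(x, ...) {
  cat(sprintf("sim_landscape: %d genes, %d enhancer peaks, %d loops, %d features\n",
              nrow(x$tss), nrow(x$enhancers), nrow(x$loops),
              ncol(x$promoter_signal)))
  inf <- names(x$feature_targets)[!is.na(x$feature_targets)]
  cat(sprintf("  informative features: %s\n",
              if (length(inf)) paste(inf, collapse = ", ") else "none"))
  invisible(x)
}

#' Write landscape files to disk
#'
#' Emits `tss.tsv`, `promoter_signal.tsv`, `enhancers.bed`,
#' `enhancer_signal.tsv`, `loops.tsv`, `er_peaks.bed` and `truth.tsv`.
#'
#' @param x a `sim_landscape`
#' @param dir output directory
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(x, dir) {
  stopifnot(inherits(x, "sim_landscape"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f, col.names = TRUE) {
    utils::write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = col.names)
  }
  wt(x$tss, "tss.tsv")
  wt(data.frame(gene = rownames(x$promoter_signal), x$promoter_signal,
                check.names = FALSE), "promoter_signal.tsv")
  wt(x$enhancers[, c("chrom", "start", "end", "peak_id", "gene")],
     "enhancers.bed", col.names = FALSE)
  wt(data.frame(peak_id = rownames(x$enhancer_signal), x$enhancer_signal,
                check.names = FALSE), "enhancer_signal.tsv")
  wt(x$loops, "loops.tsv")
  wt(x$er_peaks, "er_peaks.bed", col.names = FALSE)
  wt(x$truth, "truth.tsv")
  invisible(dir)
}
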