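iv <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("half-open interval overlap boundary cases", {
  expect_false(interval_overlap(iv("c", 0, 100), iv("c", 100, 200)))
  expect_true(interval_overlap(iv("c", 0, 100), iv("c", 99, 200)))
  expect_false(interval_overlap(iv("c1", 0, 100), iv("c2", 0, 100)))
})

test_that("loop filtering matches the read/FDR boundary rules", {
  loops <- data.frame(chrom1 = "c", start1 = 0, end1 = 10,
                      chrom2 = "c", start2 = 100, end2 = 110,
                      reads = c(2, 3, 100, 10),
                      fdr = c(0.01, 0.049, 0.05, 0.2))
  kept <- filter_loops(loops)
  expect_identical(kept$reads, 3)   # reads=2 removed; fdr>=0.05 removed
  expect_identical(kept$fdr, 0.049) # boundary of both rules retained
  # idempotent subset
  expect_identical(filter_loops(kept), kept)
  loops$reads[1] <- -1
  expect_error(filter_loops(loops), "negative")
})

test_that("promoters are 500 bp windows centered on the strand-aware TSS", {
  tab <- data.frame(gene = c("a", "b", "c"), chrom = "c",
                    tx_start = c(10000, 100, 5000),
                    tx_end = c(20000, 1100, 8000),
                    strand = c("+", "+", "-"))
  pr <- define_promoters(tab)
  expect_equal(pr$start[pr$gene == "a"], 9750)
  expect_equal(pr$end[pr$gene == "a"], 10250)
  # clamped at zero
  expect_equal(pr$start[pr$gene == "b"], 0)
  expect_equal(pr$end[pr$gene == "b"], 350)
  # minus strand: TSS at transcript end
  expect_equal(pr$start[pr$gene == "c"], 7750)
  expect_equal(pr$end[pr$gene == "c"], 8250)
  tab$strand <- NULL
  expect_error(define_promoters(tab), "strand")
})

test_that("enhancer linking matches hand-built loop topologies", {
  pr <- data.frame(gene = "g1", chrom = "c", start = 9750, end = 10250)
  peaks <- iv("c", c(50000, 50400, 70000), c(50300, 50700, 70100))
  peaks$peak_id <- c("p1", "p2", "p3")
  # one loop, distal anchor covering two peaks
  loops <- data.frame(chrom1 = "c", start1 = 9500, end1 = 10500,
                      chrom2 = "c", start2 = 49900, end2 = 50800)
  links <- link_enhancers(pr, loops, peaks)
  expect_identical(sort(links$g1$peak_id), c("p1", "p2"))
  # two loops sharing a distal peak count it once
  loops2 <- rbind(loops, loops)
  links2 <- link_enhancers(pr, loops2, peaks)
  expect_identical(attr(links2, "n_enhancers")[["g1"]], 2L)
  # no loop touching the promoter
  far <- data.frame(chrom1 = "c", start1 = 90000, end1 = 91000,
                    chrom2 = "c", start2 = 49900, end2 = 50800)
  expect_identical(attr(link_enhancers(pr, far, peaks),
                        "n_enhancers")[["g1"]], 0L)
})

test_that("enhancer linking and ER counting agree with brute force", {
  set.seed(9)
  for (rep in 1:5) {
    pr <- random_intervals(20)
    pr$gene <- paste0("g", seq_len(nrow(pr)))
    loops_a <- random_intervals(60)
    loops_b <- random_intervals(60)
    loops <- data.frame(chrom1 = loops_a$chrom, start1 = loops_a$start,
                        end1 = loops_a$end, chrom2 = loops_b$chrom,
                        start2 = loops_b$start, end2 = loops_b$end)
    peaks <- random_intervals(200)
    peaks$peak_id <- paste0("p", seq_len(nrow(peaks)))
    er <- random_intervals(40)

    links <- link_enhancers(pr, loops, peaks)
    o_pl1 <- brute_overlap(pr, loops_a)
    o_pl2 <- brute_overlap(pr, loops_b)
    o_pk1 <- brute_overlap(peaks, loops_a)
    o_pk2 <- brute_overlap(peaks, loops_b)
    o_ppk <- brute_overlap(pr, peaks)
    for (g in seq_len(nrow(pr))) {
      expected <- rep(FALSE, nrow(peaks))
      for (l in seq_len(nrow(loops))) {
        if (o_pl1[g, l]) expected <- expected | o_pk2[, l]
        if (o_pl2[g, l]) expected <- expected | o_pk1[, l]
      }
      expected <- expected & !o_ppk[g, ]
      expect_identical(sort(links[[pr$gene[g]]]$peak_id),
                       sort(peaks$peak_id[expected]))
      expect_identical(count_erbs(links[[pr$gene[g]]], er),
                       sum(rowSums(brute_overlap(
                         peaks[expected, , drop = FALSE], er)) > 0))
    }
  }
})

test_that("signal quantification counts any-overlap reads", {
  ints <- iv("c", c(100, 300), c(200, 400))
  reads <- iv("c", c(100, 150, 195, 200, 50), c(150, 160, 205, 250, 100))
  expect_identical(quantify_signal(ints, reads), c(3L, 0L))
  # brute-force cross-check on random data
  set.seed(4)
  q <- random_intervals(50)
  r <- random_intervals(500)
  expect_identical(quantify_signal(q, r),
                   as.integer(rowSums(brute_overlap(q, r))))
  expect_warning(quantify_signal(iv("cX", 1, 5), reads), "cX")
})

test_that("feature Z-scoring standardizes columns and flags degeneracy", {
  m <- cbind(a = c(0, 2, 4), b = c(1, 1, 1))
  expect_warning(z <- zscore_features(m), "zero-variance")
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_identical(unname(z[, "b"]), c(0, 0, 0))
  set.seed(5)
  z2 <- zscore_features(matrix(rnorm(500), 100, 5))
  expect_lt(max(abs(colMeans(z2))), 1e-12)
  expect_lt(max(abs(apply(z2, 2, sd) - 1)), 1e-12)
})

test_that("enhancer score follows sum log2(s+1) with the epsilon clamp", {
  expect_equal(enhancer_score(c(1, 3)), 3)
  expect_identical(enhancer_score(numeric(0)), 0)
  expect_equal(enhancer_score(-0.5), -1)
  # s <= -1 clamps at 2^-10
  expect_equal(enhancer_score(-2), -10)
  expect_identical(enhancer_score(-2, drop_low = TRUE), 0)
  # additivity and monotonicity
  set.seed(6)
  s <- rnorm(20)
  expect_equal(enhancer_score(s),
               enhancer_score(s[1:7]) + enhancer_score(s[8:20]),
               tolerance = 1e-12)
  expect_gt(enhancer_score(s + c(0.5, rep(0, 19))), enhancer_score(s))
})

test_that("gene length uses the longest transcript", {
  tx <- data.frame(gene = c("a", "b", "b"), tx_start = c(1000, 0, 100),
                   tx_end = c(4000, 2000, 5100))
  gl <- gene_length(tx)
  expect_equal(unname(gl["a"]), 3000)
  expect_equal(unname(gl["b"]), 5000)
  tx$tx_end[1] <- 1000
  expect_error(gene_length(tx), "zero-")
})

test_that("profile building assembles the design matrix coherently", {
  sim <- simulate_counts(sim_config(n_genes = 80, seed = 19))
  land <- simulate_regulatory_landscape(sim$truth,
                                        feature_names = c("F1", "F2"),
                                        informative_features = "F1",
                                        seed = 19)
  prof <- build_regulatory_profiles(land$tss, land$promoter_signal,
                                    land$enhancers, land$enhancer_signal,
                                    land$loops, land$er_peaks)
  feats <- prof$features
  expect_identical(rownames(feats), land$tss$gene)
  expect_true(all(c("F1_promoter", "F1_enhancer_score", "n_enhancers",
                    "n_erbs", "gene_length") %in% colnames(feats)))
  expect_true(all(feats[, "n_erbs"] <= feats[, "n_enhancers"]))
  # genes without enhancers score 0
  none <- feats[, "n_enhancers"] == 0
  expect_gt(sum(none), 0)
  expect_true(all(feats[none, "F1_enhancer_score"] == 0))
  # planted counts survive the loop/link round trip
  expect_identical(as.integer(feats[, "n_enhancers"]),
                   land$truth$n_enhancers_planted)
})
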