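test_that("the binomial decision rule has the documented boundary", {
  # hits = iters confirms from 6 iterations on (2 * 0.5^6 < 0.05)
  expect_identical(trajnoise:::boruta_decision(5, 5), "Tentative")
  expect_identical(trajnoise:::boruta_decision(6, 6), "Confirmed")
  expect_identical(trajnoise:::boruta_decision(0, 6), "Rejected")
  expect_identical(trajnoise:::boruta_decision(3, 6), "Tentative")
})

test_that("an informative feature is confirmed and noise rejected", {
  set.seed(1)
  n <- 500
  y <- factor(sample(c("A", "B"), n, TRUE))
  X <- cbind(signal = as.numeric(y) + rnorm(n, 0, 0.3),
             matrix(rnorm(n * 20), n, 20,
                    dimnames = list(NULL, paste0("noise", 1:20))))
  rk <- boruta_rank(X, y, seed = 1)
  expect_identical(rk$decision[rk$feature == "signal"], "Confirmed")
  expect_gte(mean(rk$decision[rk$feature != "signal"] == "Rejected"), 0.9)
  # only real features are reported; shadows never appear
  expect_identical(sort(rk$feature), sort(colnames(X)))
  expect_false(any(grepl("^shadow_", rk$feature)))
})

test_that("duplicated informative features are both confirmed", {
  set.seed(2)
  n <- 400
  y <- factor(sample(c("A", "B"), n, TRUE))
  sig <- as.numeric(y) + rnorm(n, 0, 0.3)
  X <- cbind(sig1 = sig, sig2 = sig,
             matrix(rnorm(n * 5), n, 5,
                    dimnames = list(NULL, paste0("noise", 1:5))))
  rk <- boruta_rank(X, y, seed = 2)
  expect_identical(rk$decision[rk$feature == "sig1"], "Confirmed")
  expect_identical(rk$decision[rk$feature == "sig2"], "Confirmed")
})

test_that("ranking is deterministic and permutation-equivariant", {
  set.seed(3)
  n <- 300
  y <- factor(sample(c("A", "B"), n, TRUE))
  X <- cbind(signal = as.numeric(y) + rnorm(n, 0, 0.3),
             matrix(rnorm(n * 6), n, 6,
                    dimnames = list(NULL, paste0("noise", 1:6))))
  r1 <- boruta_rank(X, y, seed = 9)
  r2 <- boruta_rank(X, y, seed = 9)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # shuffled column order: the same features end up decided the same way
  perm <- c(4, 1, 7, 2, 6, 3, 5)
  r3 <- boruta_rank(X[, perm], y, seed = 9)
  d1 <- setNames(r1$decision, r1$feature)
  d3 <- setNames(r3$decision, r3$feature)
  expect_identical(d1["signal"], d3["signal"])
  expect_identical(sort(names(d1)), sort(names(d3)))
})

test_that("degenerate ranking inputs are rejected", {
  X <- matrix(rnorm(100), 50, 2)
  expect_error(boruta_rank(X, rep("A", 50)), "2 classes")
  X[1, 1] <- NA
  expect_error(boruta_rank(X, rep(c("A", "B"), 25)), "missing")
})

test_that("decision tree splits separable data at the threshold", {
  x <- c(rnorm(200, 0), rnorm(200, 10))
  y <- rep(c("lo", "hi"), each = 200)
  tree <- fit_decision_tree(matrix(x, dimnames = list(NULL, "f")), y)
  st <- tree$structure
  expect_false(st$leaf)
  expect_identical(st$feature, "f")
  expect_gt(st$threshold, 2)
  expect_lt(st$threshold, 8)
  expect_true(st$left$leaf && st$right$leaf)
  expect_equal(sum(st$counts), 400)
})

test_that("decision tree respects leaf size and prunes pure noise", {
  set.seed(4)
  X <- matrix(rnorm(300 * 4), 300, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- sample(c("A", "B"), 300, TRUE)
  # complexity pruning collapses chance splits on pure noise once cp
  # exceeds the resubstitution optimism of the best chance split
  tree <- fit_decision_tree(X, y, complexity = 0.2)
  expect_true(tree$structure$leaf)
  expect_false(fit_decision_tree(X, y, complexity = 0.001)$structure$leaf)

  # every leaf >= min_leaf on informative data
  y2 <- ifelse(X[, 1] + rnorm(300, 0, 0.5) > 0, "A", "B")
  tree2 <- fit_decision_tree(X, y2, min_leaf = 50)
  leaf_sizes <- function(node) {
    if (node$leaf) return(node$n)
    c(leaf_sizes(node$left), leaf_sizes(node$right))
  }
  expect_true(all(leaf_sizes(tree2$structure) >= 50))
  # leaves partition the sample
  expect_equal(sum(leaf_sizes(tree2$structure)), 300)

  # min_leaf > n/2 forces a single leaf
  tree3 <- fit_decision_tree(X, y2, min_leaf = 200)
  expect_true(tree3$structure$leaf)
})

test_that("group summaries average Z-scores with sane intervals", {
  set.seed(5)
  Z <- zscore_features(matrix(rnorm(600), 200, 3,
                              dimnames = list(NULL, c("a", "b", "c"))))
  # one group holding all genes has mean ~0 for every Z-scored feature
  gs <- group_feature_summary(Z, rep("all", 200))
  expect_lt(max(abs(gs$mean)), 1e-12)
  # planted +2 SD shift is recovered as a group difference
  grp <- rep(c("x", "y"), each = 100)
  Z2 <- Z
  Z2[grp == "x", "a"] <- Z2[grp == "x", "a"] + 2
  gs2 <- group_feature_summary(Z2, grp)
  d <- gs2$mean[gs2$feature == "a" & gs2$group == "x"] -
    gs2$mean[gs2$feature == "a" & gs2$group == "y"]
  expect_equal(d, 2, tolerance = 0.5)
  # singleton group: mean defined, interval flagged NA
  gs3 <- group_feature_summary(Z, c("solo", rep("rest", 199)))
  expect_true(all(is.na(gs3$ci_lo[gs3$group == "solo"])))
  expect_false(anyNA(gs3$mean))
})

test_that("promoter/enhancer summary uses confirmed non-count features", {
  sim <- simulate_counts(sim_config(n_genes = 400, seed = 26))
  land <- simulate_regulatory_landscape(
    sim$truth, feature_names = c("F1", "F2", "F3"),
    informative_features = c("F1", "F2"), assoc_strength = 3, seed = 26)
  prof <- build_regulatory_profiles(land$tss, land$promoter_signal,
                                    land$enhancers, land$enhancer_signal,
                                    land$loops, land$er_peaks)
  labels <- sim$truth$trajectory
  rk <- boruta_rank(prof$features, labels, n_trees = 150, seed = 26)
  # force the count features into the confirmed set: they must still be
  # excluded from the promoter/enhancer averages
  rk$decision[rk$feature %in% c("n_enhancers", "n_erbs", "gene_length")] <-
    "Confirmed"
  ps <- promoter_vs_enhancer_summary(prof, labels, rk)
  expect_true(all(ps$n_promoter_features + ps$n_enhancer_features <=
                    sum(rk$decision == "Confirmed") - 3))
  expect_identical(sort(unique(ps$group)), sort(unique(labels)))

  # with a single confirmed promoter feature the summary equals that
  # feature's group mean
  rk2 <- rk
  rk2$decision[] <- "Rejected"
  rk2$decision[rk2$feature == "F1_promoter"] <- "Confirmed"
  ps2 <- promoter_vs_enhancer_summary(prof, labels, rk2)
  for (g in unique(labels)) {
    expect_equal(ps2$mean_promoter_z[ps2$group == g],
                 mean(prof$features[labels == g, "F1_promoter"]))
  }
  rk2$decision[] <- "Rejected"
  expect_error(promoter_vs_enhancer_summary(prof, labels, rk2),
               "no confirmed")
})
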