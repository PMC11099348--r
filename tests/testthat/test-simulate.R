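test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 50, n_cells_per_timepoint = 20, seed = 42)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(as.matrix(a$counts$matrix), as.matrix(b$counts$matrix))
  expect_identical(a$truth, b$truth)
  # and the caller's RNG stream is untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); simulate_counts(cfg); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("no-effect configuration plants only Null genes with flat means", {
  cfg <- sim_config(n_genes = 60, n_cells_per_timepoint = 400,
                    effect_size = 1, seed = 3)
  sim <- simulate_counts(cfg)
  expect_true(all(sim$truth$trajectory == "Null"))
  m <- sim$counts$matrix
  tp <- sim$counts$cell_meta$time_h
  mu_t <- sapply(sort(unique(tp)), function(t)
    Matrix::rowMeans(m[, tp == t, drop = FALSE]))
  # per-gene means agree across time points within sampling error
  rel_spread <- apply(mu_t, 1, function(x) diff(range(x)) / mean(x))
  expect_lt(median(rel_spread), 0.35)
})

test_that("dispersion -> 0 limit approaches the Poisson CV at matched means", {
  # closed form: CV = 1/sqrt(mean) for Poisson counts
  for (mean_val in c(10, 100)) {
    cfg <- sim_config(n_genes = 40, n_cells_per_timepoint = 2500,
                      baseline_log_mean_mu = log(mean_val),
                      baseline_log_mean_sigma = 0,
                      dispersion_low = 1e-8, dispersion_high = 1e-8,
                      library_size_sigma = 0, effect_size = 1, seed = 8)
    sim <- simulate_counts(cfg)
    m <- as.matrix(sim$counts$matrix)
    cv <- apply(m, 1, sd) / rowMeans(m)
    expect_equal(mean(cv), 1 / sqrt(mean_val), tolerance = 0.05)
  }
})

test_that("NB mean-variance relation holds at large cell numbers", {
  cfg <- sim_config(n_genes = 200, n_cells_per_timepoint = 1250,
                    effect_size = 1, dispersion_low = 0.2,
                    dispersion_high = 0.8, library_size_sigma = 0, seed = 9)
  sim <- simulate_counts(cfg)
  m <- as.matrix(sim$counts$matrix)
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  expected <- mu + sim$truth$dispersion * mu^2
  big <- mu > 1 # relative comparison is meaningful away from zero
  rel_err <- abs(v[big] - expected[big]) / expected[big]
  expect_lt(median(rel_err), 0.10)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_genes = 0), "positive integer")
  expect_error(sim_config(effect_size = 0.5), "effect_size")
  expect_error(sim_config(trajectory_fractions = c(0.5, 0.5, 0.3, 0.2)),
               "sum to")
})

test_that("landscape group-mean difference recovers the planted shift", {
  sim <- simulate_counts(sim_config(n_genes = 1000, seed = 21))
  land <- simulate_regulatory_landscape(
    sim$truth, feature_names = c("A", "B", "C", "D"),
    informative_features = "A", assoc_strength = 2, seed = 21)
  tgt <- land$feature_targets[["A"]]
  in_grp <- sim$truth$trajectory == tgt
  d <- mean(land$promoter_signal[in_grp, "A"]) -
    mean(land$promoter_signal[!in_grp, "A"])
  expect_equal(d, 2, tolerance = 0.2)
  # non-associated feature is label independent
  d0 <- mean(land$promoter_signal[in_grp, "C"]) -
    mean(land$promoter_signal[!in_grp, "C"])
  expect_lt(abs(d0), 0.5)
})

test_that("null landscape (assoc_strength 0) carries no label information", {
  sim <- simulate_counts(sim_config(n_genes = 400, seed = 22))
  land <- simulate_regulatory_landscape(
    sim$truth, feature_names = c("A", "B"), informative_features = "A",
    assoc_strength = 0, seed = 22)
  tgt <- land$feature_targets[["A"]]
  in_grp <- sim$truth$trajectory == tgt
  p <- wilcox.test(land$promoter_signal[in_grp, "A"],
                   land$promoter_signal[!in_grp, "A"])$p.value
  expect_gt(p, 0.001)
})

test_that("genes planted without enhancers have no loops to their promoter", {
  sim <- simulate_counts(sim_config(n_genes = 200, seed = 23))
  land <- simulate_regulatory_landscape(sim$truth, feature_names = "A",
                                        informative_features = "A",
                                        seed = 23)
  zero <- land$truth$gene[land$truth$n_enhancers_planted == 0]
  expect_gt(length(zero), 0) # Poisson(2) over 200 genes guarantees some
  promoters <- define_promoters(land$tss)
  links <- link_enhancers(promoters, filter_loops(land$loops),
                          land$enhancers)
  expect_true(all(attr(links, "n_enhancers")[zero] == 0))
})

test_that("unknown informative feature names are rejected", {
  sim <- simulate_counts(sim_config(n_genes = 50, seed = 1))
  expect_error(
    simulate_regulatory_landscape(sim$truth, feature_names = "A",
                                  informative_features = "NOPE"),
    "unknown feature")
})

test_that("coexpression generator tracks latent_rho", {
  # independence: mean pairwise Spearman near zero
  co0 <- simulate_coexpressed_pairs(100, 0, 2000, seed = 31)
  norm <- log_normalize(co0$counts)
  rho0 <- pairwise_spearman(norm, co0$pairs)$rho
  expect_lt(abs(mean(rho0)), 0.02)

  # comonotone limit without count noise
  co1 <- simulate_coexpressed_pairs(20, 1, 200, count_noise = FALSE,
                                    seed = 32)
  rho1 <- pairwise_spearman(co1$expr, co1$pairs)$rho
  expect_equal(rho1, rep(1, 20))

  # rho = 0.5 planted pairs beat shuffled controls (median shift)
  co5 <- simulate_coexpressed_pairs(100, 0.5, 2000, seed = 33)
  n5 <- log_normalize(co5$counts)
  obs <- pairwise_spearman(n5, co5$pairs)$rho
  ctl <- pairwise_spearman(n5, shuffle_pairs(co5$pairs, seed = 33))$rho
  expect_gt(median(obs), median(ctl))
  expect_error(simulate_coexpressed_pairs(10, 1.5, 100), "latent_rho")
})

test_that("perturbation curves have the planted midpoint and shape", {
  tc <- simulate_perturbation_timecourse(4, max_level = 2, noise_sd = 0,
                                         replicates = 1, seed = 41)
  cv <- loess_fit(tc$time_h, tc$rel_expr)
  expect_equal(cv$half_max_time, 4, tolerance = 0.1)

  flat <- simulate_perturbation_timecourse(4, max_level = 0, noise_sd = 0,
                                           replicates = 2, seed = 42)
  expect_true(all(flat$rel_expr == 0))
  expect_error(simulate_perturbation_timecourse(4, replicates = 0),
               "replicates")
  expect_error(simulate_perturbation_timecourse(20, timepoints = 0:8),
               "within the time range")
})
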