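#' Simulate co-expressed gene pairs with loop annotations
#'
#' Each planted pair shares a per-cell latent factor: the two genes' log
#' means are bivariate normal with correlation `latent_rho`, so the
#' expected rank correlation of the resulting counts increases in
#' `latent_rho`. Matching promoter-promoter loop annotations are emitted
#' for the planted pairs on the `chrS` synthetic genome (genes spaced
#' 100 kb; intervals 0-based half-open).
#'
#' @param n_pairs number of planted pairs (2 * n_pairs genes).
#' @param latent_rho latent correlation in `[0, 1]`.
#' @param n_cells number of cells.
#' @param base_mean mean count scale of every gene.
#' @param sigma sdlog of the per-cell latent expression factor.
#' @param count_noise if `FALSE`, return the continuous latent means
#'   instead of Poisson counts (the no-count-noise limit, where
#'   `latent_rho = 1` gives Spearman exactly 1).
#' @param seed integer seed.
#' @return list with `counts` (a [cell_counts()] at a single 0-h time
#'   point; `NULL` when `count_noise = FALSE`), `expr` (the gene x cell
#'   value matrix actually drawn), `pairs` (data.frame `gene_a`,
#'   `gene_b`, `latent_rho`), `tss` and `loops` (promoter-promoter loop
#'   table for the planted pairs).
#' @export
simulate_coexpressed_pairs <- function(n_pairs, latent_rho, n_cells,
                                       base_mean = 5, sigma = 1,
                                       count_noise = TRUE, seed = 1L) {
  if (!is_count(n_pairs) || !is_count(n_cells)) {
    stopf("n_pairs and n_cells must be positive integers")
  }
  if (!is.numeric(latent_rho) || latent_rho < 0 || latent_rho > 1) {
    stopf("latent_rho must lie in [0, 1]")
  }
  with_seed(op_seed(seed, 2L), {
    ng <- 2L * n_pairs
    genes <- paste0("gene", seq_len(ng))
    a_idx <- seq(1L, ng, by = 2L)
    b_idx <- a_idx + 1L

    # bivariate normal latent factors per pair
    z_a <- matrix(stats::rnorm(n_pairs * n_cells), n_pairs)
    z_i <- matrix(stats::rnorm(n_pairs * n_cells), n_pairs)
    z_b <- latent_rho * z_a + sqrt(1 - latent_rho^2) * z_i

    mu <- matrix(0, ng, n_cells)
    mu[a_idx, ] <- base_mean * exp(sigma * z_a - sigma^2 / 2)
    mu[b_idx, ] <- base_mean * exp(sigma * z_b - sigma^2 / 2)

    m <- if (count_noise) {
      matrix(stats::rpois(length(mu), mu), ng, n_cells)
    } else {
      mu # continuous latent limit (monotone in the shared factor)
    }
    rownames(m) <- genes

    meta <- data.frame(barcode = sprintf("cell%05d", seq_len(n_cells)),
                       time_h = 0, cell_line = "SIM",
                       stringsAsFactors = FALSE)
    cc <- if (count_noise) cell_counts(m, meta, genes = genes) else NULL

    pairs <- data.frame(gene_a = genes[a_idx], gene_b = genes[b_idx],
                        latent_rho = latent_rho, stringsAsFactors = FALSE)

    tss <- data.frame(gene = genes, chrom = "chrS",
                      tss = (seq_len(ng) - 1L) * 100000L + 50000L,
                      strand = "+", stringsAsFactors = FALSE)
    pa <- tss$tss[a_idx]
    pb <- tss$tss[b_idx]
    loops <- data.frame(chrom1 = "chrS", start1 = pa - 500L, end1 = pa + 500L,
                        chrom2 = "chrS", start2 = pb - 500L, end2 = pb + 500L,
                        reads = 10L, fdr = 0.001, stringsAsFactors = FALSE)
    list(counts = cc, expr = m, pairs = pairs, tss = tss, loops = loops)
  })
}

#' Simulate a sigmoidal perturbation time course
#'
#' Logistic mean curve `max_level / (1 + exp(-steepness * (t - half_max_h)))`
#' sampled at `timepoints` for `replicates` replicates with additive
#' Gaussian noise, the shape of a qPCR relative-expression trajectory
#' after stimulus.
#'
#' @param half_max_h logistic midpoint (hours), within the time range.
#' @param max_level plateau level (0 gives a flat zero curve).
#' @param noise_sd Gaussian noise SD on the expression scale.
#' @param replicates number of replicates (>= 1).
#' @param timepoints sampling times in hours.
#' @param steepness logistic slope parameter (per hour).
#' @param condition label stored in the output.
#' @param seed integer seed.
#' @return data.frame with `condition`, `replicate`, `time_h`, `rel_expr`.
#' @export
simulate_perturbation_timecourse <- function(half_max_h, max_level = 1,
                                             noise_sd = 0, replicates = 3,
                                             timepoints = 0:8,
                                             steepness = 2,
                                             condition = "targeted",
                                             seed = 1L) {
  if (!is_count(replicates)) stopf("replicates must be a positive integer")
  if (half_max_h < min(timepoints) || half_max_h > max(timepoints)) {
    stopf("half_max_h must lie within the time range")
  }
  with_seed(op_seed(seed, 3L), {
    grid <- expand.grid(time_h = timepoints, replicate = seq_len(replicates),
                        KEEP.OUT.ATTRS = FALSE)
    mu <- max_level / (1 + exp(-steepness * (grid$time_h - half_max_h)))
    data.frame(condition = condition,
               replicate = grid$replicate,
               time_h = grid$time_h,
               rel_expr = mu + stats::rnorm(nrow(grid), 0, noise_sd),
               stringsAsFactors = FALSE)
  })
}
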