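# trajnoise

Analysis of stimulus-response time courses in single-cell RNA-seq,
joined to the responding genes' cis-regulatory repertoires. The
motivating system is the transcriptional response to 17β-estradiol
(E2) through estrogen receptor α in hormone-responsive cancer cells,
profiled at 0, 2, 4 and 8 h of treatment — but every component is
generic to short stimulation time courses with a 0-h baseline.

The package is for computational biologists who want to ask, for each
gene in such an experiment:

* **When does it respond?** Genes are classified into temporal
  trajectories with two-sided Wilcoxon rank-sum tests of each treated
  time point against baseline (no fold-change cutoff): significant by
  2 h → *Early Up/Down*; first significant at 4 or 8 h →
  *Late Up/Down*; otherwise *Not Regulated*.
* **How noisy is it?** Cell-to-cell variability is quantified as a
  mean-adjusted coefficient of variation: the residual, back on the CV
  scale, of a GAM fit (`log2(CV + 1) ~ s(mean, bs = "cs")`) — so that
  High/Medium/Low noise labels (20/60/20 within each of 10 mean bins)
  are not mean-expression labels in disguise.
* **Which regulatory features predict it?** Promoter windows (500 bp
  on the TSS), loop-linked enhancers (peaks on the distal anchors of
  read/FDR-filtered loops), per-feature Z-scores, the aggregate
  enhancer score `sum(log2(s + 1))`, enhancer and ER-binding-site
  counts, and gene length feed a shadow-feature (Boruta-style)
  random-forest ranking implemented from first principles: per
  iteration, every feature must beat the best of its shuffled shadow
  copies, and a binomial test on the hit count confirms or rejects it.
* **Do connected genes co-fluctuate?** Pairwise Spearman correlation
  across cells for promoter–promoter-looped and shared-enhancer gene
  pairs, against derangement-shuffled pair nulls with
  Bonferroni-corrected Wilcoxon tests.
* **Does perturbing an enhancer change response timing?** ΔΔCt
  relative expression from qPCR tables, per-replicate loess fits,
  time to half-maximal expression, slope differentials, and one-sided
  t-tests of targeted versus control half-max times.

A negative-binomial synthetic-data generator with planted ground truth
(trajectory classes, dispersion classes, feature associations,
co-expressed pairs, sigmoid perturbation curves) stands in for the
deposited sequencing data and gives every stage a parameter-recovery
test. See the methods vignette
(`vignettes/regulatory-timing-noise.Rmd`) for the models, defaults and
design decisions.

## Worked example

```r
library(trajnoise)

sim  <- simulate_counts(sim_config(n_genes = 500,
                                   n_cells_per_timepoint = 200,
                                   seed = 42))
sim$counts
#> cell_counts: 500 genes x 800 cells
#>   time points (h): 0, 2, 4, 8
#>   cell lines: SIM

norm  <- log_normalize(filter_cells(sim$counts,
           qc_thresholds(min_reads = 50, max_reads = 1e7,
                         min_genes = 5,  max_genes = 1e6)))
calls <- classify_trajectories(norm, sim$counts$cell_meta$time_h)
calls
#> trajectory_calls: 500 genes
#>    EarlyDown      EarlyUp     LateDown       LateUp NotRegulated
#>           40           41           43           40          336
```

With 10% of genes planted per regulated class (50 genes each), the
calls recover the truth with 4-way balanced accuracy 0.82 at this
small scale (0.95+ at the 1,000-gene / 300-cell validation scale).
The noise table on the untreated cells:

```r
st <- gene_stats(norm, ifelse(sim$counts$cell_meta$time_h == 0,
                              "0h", "treated"))
nz <- noise_table(st[st$group == "0h", ])
head(nz[, c("gene", "mean", "cv", "adjusted_cv", "mean_bin", "label")], 3)
#>    gene     mean        cv adjusted_cv mean_bin  label
#> 1 gene1 3.821955 0.1480030 -0.04524556       10 Medium
#> 2 gene2 1.576041 0.7857821 -0.03689998        4 Medium
#> 3 gene3 2.543560 0.4199038 -0.06042775        8 Medium
table(nz$label)
#>   High    Low Medium
#>    100    100    300
```

`adjusted_cv` is the gene's CV minus the CV expected at its mean; the
20/60/20 label budget is exact within every mean bin. Downstream,
`simulate_regulatory_landscape()` + `build_regulatory_profiles()`
produce the gene × feature design matrix for `boruta_rank()` and
`fit_decision_tree()`, and `run_pipeline(default_run_config(seed = 1))`
chains all eight stages (simulate → preprocess → trajectory → noise →
regulatory → rank → coexpr → timing) into TSV artifacts plus a JSON
manifest, byte-identical under a fixed seed. A thin command-line
wrapper lives at `inst/scripts/run_pipeline.R`.

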