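---
title: "Trajectories, noise, and cis-regulatory features: methods and design"
author: "trajnoise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectories, noise, and cis-regulatory features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajnoise)
```

# The analysis in one paragraph

A stimulus (17β-estradiol acting through estrogen receptor α is the
motivating system) reshapes a transcriptome over a handful of hours.
Profiled with single-cell RNA-seq at 0, 2, 4 and 8 h, every gene offers
three read-outs: *how much* it is expressed, *when* it responds, and
*how variably* it is expressed from cell to cell. `trajnoise`
implements a pipeline that quantifies all three, connects them to a
gene's cis-regulatory repertoire (promoter signal, loop-linked
enhancers), ranks which regulatory features predict each read-out with
a shadow-feature random-forest algorithm, measures single-cell
co-expression of loop-connected gene pairs against shuffled-pair
nulls, and analyses perturbation (qPCR) time courses for shifts in
response timing. Because the package is developed and validated
against synthetic data with planted ground truth, every stage has a
parameter-recovery test surface.

# Temporal trajectory classification

For each gene and each treated time point, the single-cell expression
distribution is compared against the 0-h baseline with a two-sided
Wilcoxon rank-sum test. No fold-change cutoff is applied anywhere:
significance alone drives the calls. Labels follow an
Early-precedence rule:

* significant at 2 h → **EarlyUp**/**EarlyDown** (by the sign of the
  mean shift at 2 h), even when later time points are also significant;
* otherwise significant at 4 or 8 h → **LateUp**/**LateDown**, with
  direction taken at the earliest significant late time point;
* otherwise **NotRegulated**.

The rank-sum test is computed by exhaustive enumeration of all
`choose(n+m, n)` rank assignments when both groups have at most 8
observations (exact even under ties) and otherwise by the normal
approximation with tie and continuity correction. The exact threshold
of 8 keeps the enumeration below `choose(16, 8) = 12870` assignments.

**Multiplicity.** The underlying study states the test but not the
correction; we adjust p-values across genes within each time-point
contrast with Bonferroni at α = 0.05 (both configurable, with BH and
no correction as alternatives). Bonferroni is deliberately
conservative: it keeps Null genes out of the regulated classes at the
cost of sensitivity for weakly expressed genes.

**Direction consistency.** Direction is defined at the first
significant time point only; later sign flips do not relabel a gene.

Mean-level classes cut genes by rank into Low (bottom 20%), Medium
(middle 60%) and High (top 20%) mean expression. Ties are broken by
stable gene order so class sizes are floor-exact. Mean-matched control
genes are drawn by stratified sampling: means are cut into 10
equal-occupancy bins and NotRegulated genes are sampled per bin in
proportion to the regulated genes' bin occupancy.

# The expression-noise statistic

The raw coefficient of variation (CV = SD/mean, sample SD with n − 1)
of log-normalized expression is strongly mean-dependent in single-cell
data — dropout inflates the CV of weakly expressed genes. The noise
statistic is therefore the residual of a trend fit:

1. fit a penalized cubic regression spline with shrinkage
   (`mgcv::gam`, `y ~ s(x, bs = "cs")`, GCV-selected penalty, basis
   dimension 10) of `log2(CV + 1)` on the per-gene mean;
2. back-transform the fit and subtract on the CV scale:
   `adjusted_cv = CV − (2^fitted − 1)`.

A gene sitting exactly on the fitted trend gets adjusted CV 0, and on
data whose CV is mean-independent by construction the Spearman
correlation between adjusted CV and mean is below 0.05 in magnitude
(this is asserted by the test suite at 5,000 genes over three decades
of mean). The back-transform is a *difference* on the CV scale; a
ratio-scale alternative (`(CV+1)/2^fitted − 1`) is available behind
the `backtransform` flag, since "transformed back to the original
scale" admits both readings.

Noise labels are assigned within 10 equal-occupancy mean bins: the top
20% of adjusted CV per bin are High, the bottom 20% Low, the rest
Medium, with floor-exact tail sizes and stable tie-breaking. Binning
is by quantile (not equal width) so every bin carries the same label
budget; labels are computed per cell line on the 0-h cells.
Degenerate trend inputs (fewer than 4 distinct means) produce a
constant fit rather than an error, documented behaviour for pathological
inputs.

# Regulatory feature engineering

All interval arithmetic is BED-convention: 0-based, half-open,
any-overlap. Loops below 3 supporting reads or at FDR ≥ 0.05 are
discarded before any linking. Promoters are 500-bp windows centered on
the TSS (strand picks the transcript end that carries the TSS),
clamped at coordinate 0. Enhancers of a gene are peaks overlapping the
distal anchor of a loop whose other anchor overlaps the promoter; both
anchors are checked, peaks overlapping the promoter itself are
excluded, and peaks reached through several loops count once. Genes
with several annotated transcripts use the longest for both TSS choice
and gene length.

Per-feature signals are standardized across genes (Z-scores; a
zero-variance feature becomes an all-zero column with a warning). The
aggregate enhancer score of a gene is `sum(log2(s + 1))` over its
enhancers, `s` being the per-enhancer Z-score. Because a Z-score below
−1 makes the logarithm undefined, the argument is floored at
`2^-10`; the floor preserves the ordering of enhancer strengths while
bounding the penalty a single weak enhancer can contribute (−10 per
enhancer). Dropping such enhancers instead is available via
`drop_low = TRUE`. The design matrix for ranking carries, per gene:
promoter Z-score per feature, enhancer score per feature, the number
of enhancers, the number of ER-bound enhancers (ERBS), and gene
length.

# Shadow-feature ranking

The all-relevant feature selection loop is implemented from first
principles; only the random-forest classifier inside it is delegated
(to `ranger`, 500 trees by default, √p candidate features per split,
single-threaded for reproducibility):

1. append a shuffled "shadow" copy of every still-undecided feature;
2. fit the forest on real + shadow features;
3. importance = the Z-score of per-tree permutation importance (the
   mean importance over trees divided by its standard error — ranger's
   scaled permutation importance). Raw impurity importance is
   available behind `importance = "impurity"`; per-tree
   impurity-decrease importances are not exposed by any available
   forest backend, so the permutation Z is the default;
4. a real feature scores a hit when it beats the *maximum* shadow
   importance;
5. after every iteration, a two-sided binomial test of the hit count
   against Binomial(iterations, 1/2) at α = 0.05 confirms
   (significantly many hits) or rejects and removes (significantly
   few) the feature — a feature hitting every one of the first 6
   iterations is confirmed, since 2·0.5⁶ < 0.05;
6. stop when every feature is decided or after 100 iterations
   (the maximum the motivating study used); survivors are Tentative,
   with no rough-fix step.

Shadows are rebuilt each iteration and never reported. Decisions,
hit counts and the median importance over each feature's alive
iterations are returned, with the full importance history as an
attribute.

The companion decision tree (CART, Gini impurity, `rpart` with
minbucket 50 and cp 0.007 — the study's parameters) renders the
hierarchy of confirmed predictors. Note that cp = 0.007 is permissive:
on pure-noise features chance splits reduce resubstitution error by
more than 0.7% at realistic sample sizes, so a root-only tree on noise
requires a larger cp (the test suite demonstrates the pruning
mechanism at cp = 0.2).

Group summaries average Z-scored signal per feature per gene group
with normal-approximation 95% intervals; the promoter-versus-enhancer
summary averages only Boruta-confirmed features, splits them by
promoter/enhancer provenance, and always excludes the count-type
features (enhancer count, ERBS count, gene length) from the averages.

# Co-expression

Pair sets come from loops (promoter–promoter pairs; shared-enhancer
pairs), from trajectory groups, or from noise labels. Co-expression is
pairwise Spearman correlation across cells (average ranks under ties;
pairs with a zero-variance member are flagged undefined). Controls are
derangement-style reshuffles of the pair list: same size, no original
(unordered) pair, no self-pairs, retried up to 100 times before
erroring on tiny sets. Observed and control correlation distributions
are compared with a two-sided Wilcoxon test, Bonferroni-multiplied by
the number of parallel comparisons and capped at 1. Pairs whose genes
fall below the expression filter are excluded before correlation.

# Perturbation timing

qPCR time courses are converted to relative expression by ΔΔCt
(`2^−ΔΔCt`, ΔCt = Ct_target − Ct_reference with CTCF as the natural
reference, ΔΔCt relative to the control condition's 0-h baseline).
Each replicate's time course is fitted with loess (degree 2, tri-cube
weights, span 0.75, all defaults configurable) and evaluated on a
0.1-h grid. The time to half-maximal expression is the earliest grid
time at which the fitted curve reaches half of its *fitted* maximum
(an exact-crossing tolerance of 1e−8 relative keeps grid-aligned
crossings from floating-point misses); a flat curve reaches half-max
at the grid origin by convention. Curves are fitted per replicate
(rather than on the replicate mean) so that the one-sided two-sample
t-test of targeted versus control half-max times has replicate-level
degrees of freedom; `direction = "slower"` encodes the repression
expectation, `"faster"` activation. Slope series are finite
differences of the fitted grid values; group aggregates report the
pointwise mean and 95% interval.

# The synthetic-data generator

The generator emulates the study's data shapes with known ground
truth; its defaults are the conditions under which the package's
recovery properties are stated.

**Counts.** Negative binomial per gene × cell with variance
`mean + dispersion·mean²`; lognormal(0, 0.3) per-cell library-size
factors; 4 time points, 300 cells each by default. Baseline means are
lognormal with meanlog log(2) and sdlog 1, i.e. typical per-cell means
of roughly 0.3–15: the regime of genes that survive the standard
expression filter at 10x-like depth. Genes below assay sensitivity
are not a meaningful substrate for planting temporal effects, so the
generator does not produce them. Trajectory fractions default to 10%
per regulated class (40% regulated); effect size defaults to 2.
EarlyUp genes follow the immediate-early pulse
`(1, E, 1+(E−1)/2, 1+(E−1)/4)` across (0, 2, 4, 8) h. LateUp genes
follow `(1, 1, 1+(E−1)/2, E)`: flat at 2 h by construction, because a
Late gene is *defined* by its first detectable change arriving at 4 or
8 h — a Late profile that already moves at 2 h would be detected there
at these cell numbers and the planted truth would contradict the label
semantics. Down classes are reciprocals; Null genes are flat. Half the
genes carry low dispersion (0.1), half high (1.0), interleaved
independently of trajectory so the dispersion classes are mean-matched.

**Regulatory landscape.** A single synthetic chromosome `chrS` with
genes spaced 100 kb apart, 10-kb transcripts, enhancers placed within
±50 kb of the TSS, one loop per enhancer plus sub-threshold decoy
loops that the loop filter must remove. Designated informative
features are shifted by `assoc_strength` standard deviations between
genes of the feature's target label and all others; the rest are
label-independent N(0, 1) noise. EarlyUp genes draw more enhancers
(Poisson mean 4 versus 2) and their enhancers overlap ER peaks more
often (0.8 versus 0.3), mirroring the association of multiple
ER-bound enhancers with fast activation.

**Co-expressed pairs.** Pair members' log-means are bivariate normal
with correlation `latent_rho` per cell; counts are Poisson around the
latent means (disable `count_noise` for the comonotone limit where
`latent_rho = 1` yields Spearman exactly 1). Matching
promoter–promoter loop annotations are emitted.

**Perturbation curves.** Logistic mean curves
`max/(1 + exp(−k(t − midpoint)))` with k = 2 per hour, sampled at 0–8 h
with Gaussian noise per replicate.

**What the generator does not emulate:** doublets, ambient RNA, batch
effects, cell-cycle structure, read-level sequence error, UMI
saturation. Passing recovery tests therefore demonstrates statistical
correctness of the methods under a clean negative-binomial world, not
robustness to every artefact of real droplet data.

# Problem sizes, seeds and determinism

Every stochastic operation draws from a stream seeded by
`seed + op-specific offset` and restores the caller's RNG state, so a
single integer reproduces any run, and the full pipeline is
byte-identical under a fixed seed (asserted by hashing all artifacts
of two runs). The validation suite uses: 1,000 genes × 300 cells per
time point for trajectory recovery; 5,000 genes for the
mean-independence property; 1,500 genes × 400 cells for noise-label
recovery; 20 ranking runs with planted 2-SD features and 50
null-landscape runs, both at 1,000 genes (100-tree forests — the
hit/decision statistics stabilize well below the 500-tree default, and
the smaller forest keeps the 70-run protocol compact); 100 pairs × 2,000 cells for co-expression discrimination
with 100 null runs at 50 pairs × 400 cells; 200 simulations for
timing power. The same quantities are recomputed from scratch by
`scripts/acceptance.R`.

# Known limitations

* The Wilcoxon approximation (continuity + tie correction) differs
  from exact enumeration for group sizes just above 8; the threshold
  is configurable where exactness matters more than speed.
* Boruta-style decisions use unadjusted per-iteration binomial tests at
  α = 0.05; sequential testing across up to 100 iterations means a
  pure-noise feature with persistently lucky sample association can
  occasionally be confirmed. The null confirmation fraction is
  measured (and bounded) by the validation suite rather than derived
  analytically.
* The CV trend fit is only defined over the observed mean range;
  predictions outside it are clamped to the range boundary.
* Equal-occupancy binning guarantees label budgets per bin but makes
  bin boundaries data-dependent; labels are comparable within a run,
  not across datasets.
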