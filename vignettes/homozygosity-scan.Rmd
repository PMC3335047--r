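---
title: "Case-control homozygosity association scans with rohscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-control homozygosity association scans with rohscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
library(ggplot2)
```

## The problem

A run of homozygosity (ROH) is a contiguous stretch of homozygous genotype
calls along a chromosome. In outbred populations, long ROHs arise from
linkage disequilibrium, selection, or recent shared ancestry; if recessive
variants inside such a tract predispose to disease, affected individuals
should carry the tract more often than unaffected ones. rohscan implements a
genome-wide case-control scan for such *homozygosity disequilibrium*,
together with the simulation machinery needed to study its operating
characteristics without access to controlled genotype data.

## The statistic

For each SNP in turn (the *anchor*), a window of the `W` SNPs physically
nearest the anchor on the same chromosome is formed (the anchor plus its
`W - 1` nearest neighbours; on a sorted map this is always a contiguous
block, asymmetric near chromosome ends). Within a window, each individual's
genotype calls are reduced to homozygous/heterozygous states
(`AA, BB -> 1`, `AB -> 0`) and smoothed by a degree-1 weighted
least-squares fit of state on physical position with tricube weights

$$w_j = \left(1 - (d_j / d_{\max})^3\right)^3, \qquad
  d_j = |x_j - x_{\mathrm{anchor}}|,$$

evaluated at the anchor. The fitted value is the individual's *homozygote
intensity* at the anchor — a locally weighted fraction of homozygous SNPs —
clamped to $[\zeta, 1-\zeta]$ with $\zeta = 10^{-6}$ so that downstream
logarithms stay finite. Missing calls are excluded from the fit (the fitted
curve stands in for them); weights are always computed from the full window
geometry so that the weight function does not depend on which calls happen
to be missing. Fewer than two observed states leave the intensity missing
and the individual is dropped from that anchor's test, with a count kept in
the profile.

Each intensity $p$ is then compared with the pooled per-anchor median $q$
(cases and controls together, midpoint convention) through the Bernoulli
Kullback–Leibler distance, signed by the direction of departure:

$$D(p, q) = \operatorname{sign}(p - q)\left[p \log\frac{p}{q} +
  (1-p)\log\frac{1-p}{1-q}\right].$$

The sign matters: excess homozygosity (an ROH) and excess heterozygosity
deviate by the same unsigned distance, and only the former is of interest.
$D$ is zero exactly at $p = q$ and strictly increasing in $p$ for fixed $q$,
so ranking individuals by signed KL deviation is equivalent to ranking them
by intensity.

Case/control differences are tested per anchor with a one-sided Wilcoxon
rank-sum test (cases stochastically larger). When the smaller group exceeds
25 individuals the tie-corrected normal approximation with continuity
correction is used, computed in log space so that genome-scale significance
levels do not underflow; smaller groups get an exact p-value (complete
enumeration of case assignments under ties, the exact rank-sum distribution
otherwise). Anchors with $-\log_{10}(p)$ above a fixed genome-wide threshold
(default 8) are merged into significant regions by
`significant_regions()`.

```{r example}
cfg <- cohort_sim_config(n_cases = 200, n_controls = 300, n_snps = 400,
                         L = 80, delta = 0.5, epsilon = 0.1)
sim <- simulate_cohort(cfg, seed = 1)
scan <- roh_scan(sim, W = 40)
glance(scan)
significant_regions(scan, threshold_log10p = 8)
```

## Tunable parameters

* `W` (window size, SNPs): the resolution/stability trade-off. Small
  windows track short tracts but have noisy intensities; large windows
  smooth away tracts much shorter than `W`. Scans at several `W` (e.g. 100,
  150, 200 on a 500K-array map) are the intended usage.
* `carrier_threshold` (default 0.95): intensity at or above which an
  individual is called an ROH carrier for `pROH` summaries and category
  tables. There is no canonical value; 0.95 demands near-complete local
  homozygosity while tolerating a few percent interference.
* `threshold_log10p` (default 8): fixed genome-wide significance level on
  $-\log_{10}(p)$, deliberately a constant rather than a Bonferroni
  computation so results are comparable across maps.
* `rmin`, `smin` (run-length caller): minimum homozygous SNPs per run and
  minimum supporting individuals per SNP. Grids of
  `rmin` in {50, 100, 150, 200} and `smin` in {100, ..., 300} are typical
  for dense arrays.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure the scan assumes: `n_snps`
evenly spaced SNPs (default spacing 3,000 bp, matching dense-array
intermarker distances), per-SNP minor-allele frequencies drawn uniformly on
[0.05, 0.5], genotypes i.i.d. Hardy–Weinberg across individuals, and a
centered tract of `L` consecutive SNPs overwritten with homozygous calls in
exactly `round(delta * n_cases)` randomly chosen cases. The homozygous call
is `BB` with probability equal to the minor-allele frequency (`AA`
otherwise) so allele frequencies are preserved; each carrier tract SNP
independently reverts to `AB` with probability `epsilon` (*heterozygous
interference*: genotyping error or recent mutation inside the tract);
missingness is applied last, uniformly. The tract is placed at the centre
because, with evenly spaced SNPs and no background structure, detection is
location-invariant — a fixed location keeps replicates comparable.

What the generator deliberately does **not** emulate: linkage
disequilibrium and natural background ROHs. Real genomes carry long
homozygous tracts in controls too, which widens the background intensity
distribution and makes partially eroded tracts (large `epsilon`) harder to
distinguish than they are against an i.i.d. background. Passing tests on
synthetic cohorts therefore demonstrate the statistical machinery, not
field performance on array data; with an i.i.d. background the scan's power
is nearly insensitive to `epsilon` at moderate interference because the
background intensity spread (about 0.055 at `W = 100`) stays far below the
carrier intensity even at `epsilon = 0.2`. This is the main caveat when
comparing the package's power table against studies whose background
carries LD structure.

## The power study

`estimate_power()` draws replicate cohorts, scans them, and reports the
fraction of replicates in which any anchor whose window overlaps the tract
reaches the genome-wide threshold (`rule = "any_overlap"`, the default; a
`"center_anchor"` rule testing only the tract-centre anchor is also
provided — the two differ because the maximum over several hundred
partially correlated anchors detects marginal signals more often than any
single anchor). The background is restricted to the tract plus `2 W` SNPs
and a 100-SNP buffer per side: under a fixed per-anchor threshold,
detection depends only on windows overlapping the tract, so the local
background leaves the estimand unchanged while keeping a 5,000-individual
replicate to a fraction of a second. The tract-centre anchor is evaluated
first and clear detections exit early; each anchor's test involves no
cross-anchor quantities, so staging cannot change the result. Replicate
seeds derive from one master seed, and `power_grid()` reuses the same
replicate seeds in every cell (common random numbers), which makes the
power surface monotone in `delta` and `epsilon` replicate by replicate.
The default 200 replicates put the binomial standard error at or below
0.035; `n_replicates` raises it where sharper estimates are wanted.

```{r power, eval = FALSE}
grid <- power_grid(deltas = c(0.1, 0.2, 0.3), Ls = 200,
                   epsilons = c(0, 0.2), Ws = c(100, 150, 200),
                   n_replicates = 200, seed = 1)
autoplot(grid)
```

## Stratification adjustment

Population substructure inflates homozygosity association: a subpopulation
with elevated background homozygosity and an elevated case fraction mimics
a disease-associated ROH. `genotype_pca()` computes a plain additive-coding
PCA (columns centred and scaled by $\sqrt{\hat p(1-\hat p)}$, missing
values mean-imputed), and `adjusted_scan()` regresses the homozygote
intensity on status plus the leading components, testing the status
coefficient two-sided (the regression convention; the rank-sum scan is
one-sided by design, an asymmetry that is intentional and documented).
With no components the test reduces algebraically to the pooled-variance
two-sample t-test, which the test suite checks numerically. The intensity,
not the KL deviation, is the regression response — it is the quantity on a
stable 0–1 scale with an interpretable status coefficient.

## Run-length validation and prediction

`call_runs()` is a deliberately strict run-length ROH caller used to
cross-validate the smoothing-based scan: heterozygous calls break runs,
missing calls are skipped (they neither break a run nor count toward its
length — breaking on missingness would shatter true tracts at random,
while the heterozygote tolerance belongs to the smoother, not the caller).
`filter_snps_by_support()` and `permutation_association()` then test
case/control differences in ROH membership with label permutations; the
per-SNP statistic is the difference in membership proportions and the
region statistic its maximum over retained SNPs, with the empirical p-value
`(1 + #{perm >= obs}) / (n_perm + 1)` reported for both (the choice of
statistic is declared here, not canonical).

`lda_cv_accuracy()` predicts status from anchor intensities by linear
discriminant analysis (quadratic by option) under stratified 10-fold
cross-validation with a fixed seed. With the package's default group sizes
(2,000/3,000) a chance-level classifier sits at the majority proportion
0.6, not 0.5 — accuracies just above 0.6 should be read against that
baseline. `category_table()` cross-classifies individuals by carrier
status at a small set of tag anchors selected by
`select_tag_anchors()`, which groups contiguous anchors whose case-carrier
sets overlap (pairwise Jaccard above 0.8 by default — a computable stand-in
for visual blocking of carrier patterns) and keeps one representative per
group.

## Numerical choices and degenerate inputs

* Window positions are centred at the anchor and rescaled by $d_{\max}$
  before the WLS solve; the fitted value at the anchor is invariant to this
  rescaling and the normal-equation determinant becomes well conditioned.
* A window whose positive-weight support collapses onto a single position
  (determinant below $10^{-12}$ on the rescaled design) falls back to the
  tricube-weighted mean.
* Members at exactly $d_{\max}$ get weight zero — a window of three equally
  spaced states therefore reproduces its centre state.
* Equidistant window candidates resolve toward the lower SNP index;
  chromosomes with fewer than `W` SNPs yield truncated, flagged windows.
* All-tied rank-sum columns report p = 1, not an error; anchors where a
  group is empty after missingness propagate `NA` and are counted.
* Internal coordinates are 1-based inclusive; BED output converts to
  0-based half-open.

## Problem sizes

The test suite exercises the full study size (2,000 cases, 3,000 controls)
for the power table (200 replicates per cell over the 14-cell
delta/epsilon/W grid), null calibration (500 replicates), and tract
recovery (50 replicates); unit tests run on cohorts of tens to hundreds of
individuals. A single 5,000-individual replicate — simulation, smoothing at
~300 anchors, and the rank-sum scan — takes well under a second through the
banded matrix formulation of the WLS fit and compiled kernels for
simulation and ranking.

## Known limitations

* No LD-aware or coalescent background; see the generator caveat above.
* The PCA is LD-naive and performs no outlier removal.
* The run-length caller tolerates no heterozygous interruptions by design.
* Genome-scale maps (hundreds of thousands of SNPs) are processed
  per chromosome; the dense band matrices assume windows much smaller than
  the chromosome SNP count.
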