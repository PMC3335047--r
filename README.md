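# rohscan

Genome-wide case-control association mapping of runs of homozygosity (ROH).

A run of homozygosity is a contiguous stretch of homozygous genotype calls.
Where recessive-acting variants inside such a tract predispose to disease,
cases carry the tract more often than controls. `rohscan` scans a SNP map
for this *homozygosity disequilibrium*: for every anchor SNP it forms the
window of the `W` physically nearest SNPs, smooths each individual's
homozygous/heterozygous states (AA/BB → 1, AB → 0) with a tricube-weighted
local linear fit of state on position to get a per-individual **homozygote
intensity** `p ∈ [ζ, 1−ζ]`, converts it to a signed Bernoulli
Kullback–Leibler deviation from the pooled median intensity `q`,

    D(p, q) = sign(p − q) · [ p log(p/q) + (1−p) log((1−p)/(1−q)) ],

and tests cases against controls per anchor with a one-sided Wilcoxon
rank-sum test, reporting −log10(p) and merging anchors above a genome-wide
threshold (default −log10(p) > 8) into significant regions.

Around the scan, the package provides:

* **Synthetic cohorts** (`simulate_cohort()`): Hardy–Weinberg background at
  evenly spaced SNPs with an embedded homozygous tract of `L` SNPs carried
  by a fraction `δ` of cases, heterozygous interference `ε` inside the
  tract, and optional missingness — fully reproducible from a seed.
* **Power simulation** (`estimate_power()`, `power_grid()`): detection
  probability across the (δ, L, ε, W) grid at configurable cohort sizes,
  with common random numbers across grid cells.
* **Stratification adjustment** (`genotype_pca()`, `adjusted_scan()`):
  per-anchor regression of intensity on status plus leading genotype
  principal components.
* **Run-length validation** (`call_runs()`, `filter_snps_by_support()`,
  `permutation_association()`): a strict ROH caller with `Rmin`/`Smin`
  filters and a label-permutation association test.
* **Prediction and categories** (`lda_cv_accuracy()`,
  `predict_status_cv()`, `category_table()`, `select_tag_anchors()`):
  discriminant-analysis status prediction under stratified 10-fold
  cross-validation, and ROH-carrying category summaries over tag anchors.
* **I/O**: PLINK text `.ped`/`.map`, a genotype TSV dialect, and BED
  region export. A thin CLI lives at `inst/cli/rohscan.R`
  (`simulate`/`scan`/`power` subcommands).

## Worked example

```r
library(rohscan)

cfg <- cohort_sim_config(n_cases = 200, n_controls = 300, n_snps = 400,
                         L = 80, delta = 0.5, epsilon = 0.1)
sim <- simulate_cohort(cfg, seed = 1)
sim
#> <roh_cohort> 500 individuals x 400 SNPs on 1 chromosome(s)
#>   phenotype: CASE=200, CONTROL=300
#>   missing calls: 0.00%
#>   embedded tract: SNPs 161-240 (80 SNPs), 100 carriers

scan <- roh_scan(sim, W = 40)
glance(scan)
#> # A tibble: 1 × 5
#>   n_anchors n_excluded peak_minus_log10_p peak_snp     W
#>       <int>      <int>              <dbl> <chr>    <dbl>
#> 1       400          0               24.3 snp234      40

significant_regions(scan, threshold_log10p = 8)
#> # A tibble: 1 × 7
#>   chromosome start_bp end_bp start_snp end_snp n_anchors peak_minus_log10_p
#>   <chr>         <int>  <int> <chr>     <chr>       <int>              <dbl>
#> 1 1            477000 738000 snp159    snp246         88               24.3
```

Half of the 200 cases carry an 80-SNP tract at SNPs 161–240 (bp 483,000 to
720,000); the scan finds a single significant region whose boundaries land
within a window's width of the truth and whose peak anchor (snp234,
−log10 p ≈ 24) sits inside the tract. `autoplot(scan)` draws the
Manhattan-style profile, and `call_carriers()` / `category_table()` carry
the analysis on to carrier proportions (pROH) per group.

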