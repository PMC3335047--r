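#' Default minor-allele-frequency law
#'
#' Per-SNP minor-allele frequencies for the synthetic background are drawn
#' uniformly on \[0.05, 0.5\]: common SNPs of the kind retained on genotyping
#' arrays after rare-variant filtering.
#'
#' @return A function of `n` returning `n` MAF draws.
#' @examples
#' law <- maf_law_default()
#' range(law(1000))
#' @export
maf_law_default <- function() {
  function(n) runif(n, 0.05, 0.5)
}

#' Configure a synthetic case-control cohort
#'
#' Describes the simulation design used throughout the power study: evenly
#' spaced background SNPs in Hardy-Weinberg equilibrium, and a centered tract
#' of `L` consecutive SNPs overwritten with homozygous calls in a fraction
#' `delta` of cases. Within a carrier's tract each SNP independently reverts
#' to a heterozygous call with probability `epsilon` ("heterozygous
#' interference"); uniform missingness is applied last.
#'
#' @param n_cases,n_controls Group sizes (defaults 2000 and 3000, the study
#'   sizes the method was evaluated at).
#' @param n_snps Number of background SNPs.
#' @param spacing_bp Inter-SNP spacing in bp (default 3000, matching the
#'   ~3.2 kb mean intermarker distance of a 500K array in the target region).
#' @param maf_law Function of `n` returning per-SNP minor-allele frequencies;
#'   see [maf_law_default()].
#' @param L Tract length in SNPs.
#' @param delta Fraction of cases carrying the tract, in \[0, 1\].
#' @param epsilon Heterozygous-interference fraction inside the tract.
#' @param missing_rate Per-call missing probability.
#' @param chromosome Chromosome label for the simulated map.
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_cases = 2000, n_controls = 3000,
                              n_snps = 1000, spacing_bp = 3000,
                              maf_law = maf_law_default(),
                              L = 200, delta = 0, epsilon = 0,
                              missing_rate = 0, chromosome = "1") {
  stopifnot(n_cases >= 0, n_controls >= 0, n_snps >= 1, spacing_bp >= 1,
            is.function(maf_law), L >= 1, L <= n_snps,
            delta >= 0, delta <= 1, epsilon >= 0, epsilon <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (delta > 0 && n_cases == 0) {
    stop("delta > 0 requires at least one case", call. = FALSE)
  }
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         n_snps = as.integer(n_snps), spacing_bp = as.integer(spacing_bp),
         maf_law = maf_law, L = as.integer(L), delta = delta,
         epsilon = epsilon, missing_rate = missing_rate,
         chromosome = chromosome),
    class = "cohort_sim_config"
  )
}

#' Simulate a case-control cohort with an embedded homozygous tract
#'
#' Draws per-SNP minor-allele frequencies from `config$maf_law`, genotypes
#' all individuals i.i.d. under Hardy-Weinberg equilibrium, then overwrites a
#' centered run of `L` consecutive SNPs with homozygous calls in exactly
#' `round(delta * n_cases)` randomly chosen cases. The homozygous call at a
#' tract SNP is BB with probability equal to the minor-allele frequency, AA
#' otherwise, preserving allele frequencies. Each carrier tract SNP then
#' independently becomes AB with probability `epsilon`, and finally every
#' call is set missing with probability `missing_rate`. Bit-identical given
#' `seed`.
#'
#' @param config A [cohort_sim_config()].
#' @param seed Optional integer seed.
#' @return A `synthetic_cohort` (subclass of [roh_cohort()]) with extra
#'   elements `tract_start_idx`, `tract_end_idx`, `carrier_mask` and `maf`.
#' @examples
#' cfg <- cohort_sim_config(n_cases = 20, n_controls = 30, n_snps = 50,
#'                          L = 10, delta = 0.5)
#' sim <- simulate_cohort(cfg, seed = 1)
#' sim$tract_start_idx
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "cohort_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_cases + config$n_controls
  m <- config$n_snps
  maf <- config$maf_law(m)
  genotypes <- cpp_sim_genotypes(n, maf)

  ts <- (m - config$L) %/% 2L + 1L
  te <- ts + config$L - 1L
  n_carriers <- round(config$delta * config$n_cases)
  carrier_mask <- rep(FALSE, n)
  if (n_carriers > 0) {
    carriers <- sample.int(config$n_cases, n_carriers)
    carrier_mask[carriers] <- TRUE
    tract_maf <- maf[ts:te]
    for (i in carriers) {
      hom <- ifelse(runif(config$L) < tract_maf, 2L, 0L)
      het <- runif(config$L) < config$epsilon
      hom[het] <- 1L
      genotypes[i, ts:te] <- hom
    }
  }
  if (config$missing_rate > 0) {
    drop <- runif(length(genotypes)) < config$missing_rate
    genotypes[drop] <- NA_integer_
  }

  map <- tibble(
    snp_id = paste0("snp", seq_len(m)),
    chromosome = config$chromosome,
    position_bp = config$spacing_bp * seq_len(m)
  )
  phenotype <- rep(c("CASE", "CONTROL"),
                   c(config$n_cases, config$n_controls))
  out <- roh_cohort(genotypes, map, phenotype)
  out$tract_start_idx <- ts
  out$tract_end_idx <- te
  out$carrier_mask <- carrier_mask
  out$maf <- maf
  out$config <- config
  class(out) <- c("synthetic_cohort", class(out))
  out
}

#' Simulate a two-subpopulation stratified cohort
#'
#' A Balding-Nichols style mixture for exercising the stratification
#' adjustment: subpopulation allele frequencies are drawn around a shared
#' ancestral frequency with divergence `fst`, genotypes follow
#' Hardy-Weinberg within subpopulation with optional excess homozygosity
#' `inbreeding_f` (which shifts background homozygote intensity), and the
#' case fraction may differ between subpopulations (which confounds status
#' with ancestry).
#'
#' @param n_per_pop Length-2 integer vector of subpopulation sizes.
#' @param case_fraction Length-2 vector of case fractions per subpopulation.
#' @param n_snps Number of SNPs.
#' @param fst Divergence between subpopulation allele frequencies.
#' @param inbreeding_f Length-2 vector of within-subpopulation inbreeding
#'   coefficients.
#' @param spacing_bp,maf_law,chromosome As in [cohort_sim_config()].
#' @param seed Optional integer seed.
#' @return A [roh_cohort()] with an extra element `population` (factor).
#' @export
simulate_stratified_cohort <- function(n_per_pop = c(500, 500),
                                       case_fraction = c(0.5, 0.5),
                                       n_snps = 500, fst = 0.1,
                                       inbreeding_f = c(0, 0),
                                       spacing_bp = 3000,
                                       maf_law = maf_law_default(),
                                       chromosome = "1", seed = NULL) {
  stopifnot(length(n_per_pop) == 2, length(case_fraction) == 2,
            length(inbreeding_f) == 2, fst > 0, fst < 1)
  if (!is.null(seed)) set.seed(seed)
  p0 <- maf_law(n_snps)
  shape <- (1 - fst) / fst
  geno <- vector("list", 2L)
  for (k in 1:2) {
    pk <- stats::rbeta(n_snps, p0 * shape, (1 - p0) * shape)
    pk <- pmin(pmax(pk, 1e-3), 1 - 1e-3)
    f <- inbreeding_f[k]
    nk <- n_per_pop[k]
    u <- matrix(runif(nk * n_snps), nk, n_snps)
    pbb <- rep(pk^2 + f * pk * (1 - pk), each = nk)
    pab <- rep(2 * pk * (1 - pk) * (1 - f), each = nk)
    geno[[k]] <- (u < pbb) * 2L + (u >= pbb & u < pbb + pab) * 1L
  }
  genotypes <- rbind(geno[[1]], geno[[2]])
  population <- factor(rep(c("pop1", "pop2"), n_per_pop))
  phenotype <- unlist(lapply(1:2, function(k) {
    nk <- n_per_pop[k]
    ncase <- round(case_fraction[k] * nk)
    sample(rep(c("CASE", "CONTROL"), c(ncase, nk - ncase)))
  }))
  map <- tibble(snp_id = paste0("snp", seq_len(n_snps)),
                chromosome = chromosome,
                position_bp = spacing_bp * seq_len(n_snps))
  out <- roh_cohort(genotypes, map, phenotype)
  out$population <- population
  out
}
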