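#' Call runs of homozygosity by run length
#'
#' Per individual and chromosome, maximal runs of consecutive homozygous
#' calls are extracted. Heterozygous calls break runs; missing calls are
#' skipped — they neither break a run nor count toward its length. Runs
#' shorter than `rmin` homozygous SNPs are discarded. Calls are invariant to
#' allele relabelling (only the homozygous/heterozygous state matters).
#'
#' @param cohort A [roh_cohort()].
#' @param rmin Minimum number of homozygous SNPs per emitted run (>= 2).
#' @return A tibble of segments: `individual_id`, `status`, `chromosome`,
#'   `start_idx`, `end_idx` (global SNP indices of the first/last homozygous
#'   SNP), `start_bp`, `end_bp`, `n_snps` (homozygous SNPs in the run).
#' @examples
#' map <- tibble::tibble(snp_id = paste0("s", 1:6), chromosome = "1",
#'                       position_bp = 1:6 * 100L)
#' g <- matrix(c(0L, 0L, 2L, 1L, 0L, 2L), 1, 6) # hom,hom,hom,het,hom,hom
#' call_runs(roh_cohort(g, map), rmin = 2)
#' @export
call_runs <- function(cohort, rmin = 2) {
  stopifnot(rmin >= 2)
  S <- geno_states(cohort)
  map <- cohort$map
  chroms <- unique(map$chromosome)
  res <- vector("list", 0L)
  for (chr in chroms) {
    cols <- which(map$chromosome == chr)
    for (i in seq_len(nrow(S))) {
      st <- unname(S[i, cols])
      obs <- which(!is.na(st))
      if (length(obs) == 0L) next
      v <- st[obs]
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      hom <- which(r$values == 1 & r$lengths >= rmin)
      for (h in hom) {
        first <- cols[obs[starts[h]]]
        last <- cols[obs[ends[h]]]
        res[[length(res) + 1L]] <- list(
          individual_id = rownames(S)[i],
          status = as.character(cohort$phenotype[i]),
          chromosome = chr,
          start_idx = first, end_idx = last,
          start_bp = map$position_bp[first], end_bp = map$position_bp[last],
          n_snps = r$lengths[h]
        )
      }
    }
  }
  if (length(res) == 0L) {
    return(tibble(individual_id = character(), status = character(),
                  chromosome = character(), start_idx = integer(),
                  end_idx = integer(), start_bp = integer(),
                  end_bp = integer(), n_snps = integer()))
  }
  dplyr::bind_rows(lapply(res, as_tibble))
}

# Per-SNP count of individuals whose segment covers the SNP.
snp_roh_support <- function(segments, n_snps) {
  cov <- numeric(n_snps + 1L)
  if (nrow(segments)) {
    for (k in seq_len(nrow(segments))) {
      cov[segments$start_idx[k]] <- cov[segments$start_idx[k]] + 1
      cov[segments$end_idx[k] + 1L] <- cov[segments$end_idx[k] + 1L] - 1
    }
  }
  as.integer(cumsum(cov)[seq_len(n_snps)])
}

#' Retain SNPs supported by enough ROH-carrying individuals
#'
#' A SNP is retained when at least `smin` individuals have a called segment
#' covering it (positions between a segment's first and last homozygous SNP
#' count as covered).
#'
#' @param segments A [call_runs()] result.
#' @param smin Minimum number of supporting individuals (>= 1).
#' @param n_snps Total SNP count of the map the segments refer to.
#' @return Integer vector of retained SNP indices.
#' @export
filter_snps_by_support <- function(segments, smin, n_snps) {
  stopifnot(smin >= 1)
  which(snp_roh_support(segments, n_snps) >= smin)
}

#' Permutation test of ROH-membership association
#'
#' For each retained SNP the observed statistic is the difference in
#' ROH-membership proportions (cases minus controls); the region statistic
#' is the maximum over retained SNPs. The null distribution is built by
#' permuting phenotype labels with segments fixed, and the empirical p-value
#' is `(1 + #permutations >= observed) / (n_perm + 1)`.
#'
#' @param segments A [call_runs()] result.
#' @param phenotype Per-individual `CASE`/`CONTROL` labels, aligned with the
#'   cohort the segments were called from.
#' @param individual_ids Individual ids in cohort order (defines the rows the
#'   phenotype aligns to).
#' @param retained Retained SNP indices (see [filter_snps_by_support()]).
#' @param map The cohort SNP map (for bp coordinates in the summary).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @return A `roh_assoc_result`: list with `snp` (tibble: `snp_idx`,
#'   `snp_id`, `position_bp`, case/control membership counts, `observed`
#'   statistic and per-SNP empirical `p`), `region` (tibble with the
#'   retained-run bounds containing the maximising SNP, the observed region
#'   statistic and its empirical `p`) and `n_perm`.
#' @export
permutation_association <- function(segments, phenotype, individual_ids,
                                    retained, map, n_perm = 10000,
                                    seed = NULL) {
  phenotype <- validate_phenotype(phenotype, length(individual_ids))
  check_two_groups(phenotype)
  if (length(retained) == 0L) {
    message("no retained SNPs; empty association result")
    return(structure(list(snp = tibble(), region = tibble(),
                          n_perm = n_perm),
                     class = "roh_assoc_result"))
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(individual_ids)
  n1 <- sum(phenotype == "CASE")
  n2 <- n - n1
  M <- matrix(FALSE, n, length(retained))
  if (nrow(segments)) {
    row_of <- match(segments$individual_id, individual_ids)
    col_pos <- match(seq_len(max(retained)), retained)
    for (k in seq_len(nrow(segments))) {
      span <- segments$start_idx[k]:segments$end_idx[k]
      span <- span[span %in% retained]
      if (length(span)) M[row_of[k], col_pos[span]] <- TRUE
    }
  }
  Mn <- M + 0
  total <- colSums(Mn)
  case_counts <- colSums(Mn[phenotype == "CASE", , drop = FALSE])
  obs_snp <- case_counts / n1 - (total - case_counts) / n2
  obs_region <- max(obs_snp)

  # permute labels in blocks; case counts per SNP via one BLAS product
  block <- 1000L
  exceed_snp <- numeric(length(retained))
  exceed_region <- 0
  done <- 0L
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    P <- matrix(0, n, b)
    for (r in seq_len(b)) P[sample.int(n, n1), r] <- 1
    cc <- crossprod(Mn, P)                       # retained x b case counts
    stat <- cc / n1 - (total - cc) / n2
    exceed_snp <- exceed_snp + rowSums(stat >= obs_snp - 1e-12)
    exceed_region <- exceed_region +
      sum(apply(stat, 2L, max) >= obs_region - 1e-12)
    done <- done + b
  }
  p_snp <- (1 + exceed_snp) / (n_perm + 1)
  p_region <- (1 + exceed_region) / (n_perm + 1)

  best <- retained[which.max(obs_snp)]
  runs <- split(retained, cumsum(c(1L, diff(retained) != 1L)))
  run_of_best <- runs[[which(vapply(runs, function(r) best %in% r, logical(1)))]]
  snp_tb <- tibble(
    snp_idx = retained,
    snp_id = map$snp_id[retained],
    position_bp = map$position_bp[retained],
    n_case_roh = as.integer(case_counts),
    n_control_roh = as.integer(total - case_counts),
    observed = obs_snp,
    p = p_snp
  )
  region_tb <- tibble(
    chromosome = map$chromosome[best],
    start_bp = map$position_bp[min(run_of_best)],
    end_bp = map$position_bp[max(run_of_best)],
    peak_snp = map$snp_id[best],
    observed = obs_region,
    p = p_region
  )
  structure(list(snp = snp_tb, region = region_tb, n_perm = n_perm),
            class = "roh_assoc_result")
}

#' @export
print.roh_assoc_result <- function(x, ...) {
  cat("<roh_assoc_result> ", nrow(x$snp), " retained SNPs, ",
      x$n_perm, " permutations\n", sep = "")
  if (nrow(x$region)) {
    cat(sprintf("  region %s:%d-%d  stat = %.4f  empirical p = %.3g\n",
                x$region$chromosome, x$region$start_bp, x$region$end_bp,
                x$region$observed, x$region$p))
  }
  invisible(x)
}

#' Compare an empirical p-value against a Bonferroni level
#'
#' @param p Empirical p-value.
#' @param n_tests Number of tests in the family (>= 1).
#' @param alpha Family-wise level (default 0.05).
#' @return `TRUE` iff `p < alpha / n_tests`.
#' @examples
#' significance_vs_bonferroni(0.001, 30) # 0.001 < 0.05/30
#' @export
significance_vs_bonferroni <- function(p, n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1)
  p < alpha / n_tests
}
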