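#' One-sided Wilcoxon rank-sum test (cases larger)
#'
#' Tests whether `cases` are stochastically larger than `controls`. For small
#' groups (`min(n1, n2) <= exact_max_group`) the exact null distribution is
#' used: complete enumeration over all case-assignments of the observed
#' midranks when `choose(n, n1)` is below `enumeration_cap` (valid under
#' ties), else the tie-free `pwilcox` distribution. Larger groups use the
#' normal approximation with midranks, tie correction and continuity
#' correction, computed in log space so genome-scale significance levels
#' (`-log10 p` well above 300) do not underflow.
#'
#' @param cases,controls Numeric vectors (`NA`s dropped).
#' @param exact_max_group Largest min-group size for which an exact p-value
#'   is computed (default 25).
#' @param enumeration_cap Largest number of case-assignments enumerated.
#' @return A list with `p`, `minus_log10_p`, `statistic` (rank sum of cases)
#'   and `method`.
#' @examples
#' ranksum_test(c(3, 4, 5), c(0, 1, 2))$p  # exact 1/20
#' @export
ranksum_test <- function(cases, controls, exact_max_group = 25,
                         enumeration_cap = 2e5) {
  x <- cases[!is.na(cases)]
  y <- controls[!is.na(controls)]
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 == 0L || n2 == 0L) {
    stop("both groups need at least one non-missing value", call. = FALSE)
  }
  r <- rank(c(x, y))
  w1 <- sum(r[seq_len(n1)])
  ties <- anyDuplicated(c(x, y)) > 0L

  if (min(n1, n2) <= exact_max_group) {
    if (ties && choose(N, n1) <= enumeration_cap) {
      combs <- combn(N, n1)
      wdist <- colSums(matrix(r[combs], nrow = n1))
      p <- mean(wdist >= w1 - 1e-9)
      return(list(p = p, minus_log10_p = -log10(p), statistic = w1,
                  method = "exact enumeration"))
    }
    if (!ties) {
      u <- w1 - n1 * (n1 + 1) / 2
      p <- pwilcox(u - 1, n1, n2, lower.tail = FALSE)
      return(list(p = p, minus_log10_p = -log10(p), statistic = w1,
                  method = "exact distribution"))
    }
  }
  res <- cpp_ranksum_logp(matrix(c(x, y), ncol = 1L),
                          rep(c(TRUE, FALSE), c(n1, n2)), TRUE)
  logp <- res[1L, 1L]
  list(p = exp(logp), minus_log10_p = -logp / log(10), statistic = w1,
       method = "normal approximation")
}

#' Case/control Wilcoxon scan over anchors
#'
#' Applies the one-sided rank-sum test (cases stochastically larger) to the
#' signed Kullback-Leibler deviations at every anchor, and summarises each
#' anchor with `-log10(p)`, the per-group median intensities and the carrier
#' proportions (`pROH`) at `carrier_threshold`. Anchors where either group
#' has no non-missing deviation are reported with `NA` and counted.
#'
#' @param klp A [kl_profile()].
#' @param phenotype Optional per-individual status overriding the one stored
#'   in the profile.
#' @param carrier_threshold Intensity at or above which an individual is
#'   called an ROH carrier (default 0.95).
#' @param exact_max_group Passed to [ranksum_test()].
#' @return A `scan_result` tibble: `anchor_idx`, `snp_id`, `chromosome`,
#'   `position_bp`, `n_cases`, `n_controls`, `minus_log10_p`,
#'   `median_intensity_cases`, `median_intensity_controls`, `pROH_cases`,
#'   `pROH_controls`. The window size and carrier threshold are attributes.
#' @export
wilcoxon_scan <- function(klp, phenotype = NULL, carrier_threshold = 0.95,
                          exact_max_group = 25) {
  stopifnot(inherits(klp, "kl_profile"))
  phenotype <- validate_phenotype(phenotype %||% klp$phenotype, nrow(klp$kl))
  check_two_groups(phenotype)
  is_case <- phenotype == "CASE"

  res <- cpp_ranksum_logp(klp$kl, is_case, TRUE)
  minus_log10_p <- -res[, 1L] / log(10)
  # small effective groups (after NA removal) get the exact treatment
  redo <- which(!is.na(res[, 1L]) & pmin(res[, 3L], res[, 4L]) <= exact_max_group)
  for (j in redo) {
    rt <- ranksum_test(klp$kl[is_case, j], klp$kl[!is_case, j],
                       exact_max_group = exact_max_group)
    minus_log10_p[j] <- rt$minus_log10_p
  }

  carriers <- call_carriers(klp, threshold = carrier_threshold,
                            phenotype = phenotype)
  I <- klp$intensity
  med_case <- cpp_col_medians(I[is_case, , drop = FALSE])
  med_ctrl <- cpp_col_medians(I[!is_case, , drop = FALSE])

  out <- tibble(
    anchor_idx = klp$anchors$anchor_idx,
    snp_id = klp$anchors$snp_id,
    chromosome = klp$anchors$chromosome,
    position_bp = klp$anchors$position_bp,
    n_cases = as.integer(res[, 3L]),
    n_controls = as.integer(res[, 4L]),
    minus_log10_p = minus_log10_p,
    median_intensity_cases = med_case,
    median_intensity_controls = med_ctrl,
    pROH_cases = carriers$proh$pROH_cases,
    pROH_controls = carriers$proh$pROH_controls
  )
  class(out) <- c("scan_result", class(out))
  attr(out, "W") <- klp$W
  attr(out, "carrier_threshold") <- carrier_threshold
  attr(out, "n_anchors_excluded") <- sum(is.na(minus_log10_p))
  out
}

#' Genome-wide homozygosity association scan
#'
#' Convenience pipeline: [homozygote_intensity()] then [kl_profile()] then
#' [wilcoxon_scan()].
#'
#' @inheritParams homozygote_intensity
#' @inheritParams wilcoxon_scan
#' @return A `scan_result` tibble (see [wilcoxon_scan()]).
#' @examples
#' cfg <- cohort_sim_config(n_cases = 30, n_controls = 30, n_snps = 60,
#'                          L = 20, delta = 1)
#' sim <- simulate_cohort(cfg, seed = 1)
#' scan <- roh_scan(sim, W = 10)
#' @export
roh_scan <- function(cohort, W, anchors = NULL, carrier_threshold = 0.95,
                     exact_max_group = 25) {
  prof <- homozygote_intensity(cohort, W, anchors = anchors)
  wilcoxon_scan(kl_profile(prof), phenotype = cohort$phenotype,
                carrier_threshold = carrier_threshold,
                exact_max_group = exact_max_group)
}

#' Call ROH carriers and per-group carrier proportions
#'
#' An individual carries the ROH at an anchor when the fitted homozygote
#' intensity is at or above `threshold`; `pROH` is the carrier fraction
#' within each phenotype group (over individuals with an estimable
#' intensity).
#'
#' @param profile An [homozygote_intensity()] or [kl_profile()] result.
#' @param threshold Carrier threshold in (0, 1), default 0.95.
#' @param phenotype Optional status override.
#' @return A list with `carriers` (logical individuals x anchors matrix,
#'   `NA` where intensity is missing) and `proh` (tibble: `snp_id`,
#'   `pROH_cases`, `pROH_controls`).
#' @export
call_carriers <- function(profile, threshold = 0.95, phenotype = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  I <- profile$intensity
  phenotype <- validate_phenotype(phenotype %||% profile$phenotype, nrow(I))
  carriers <- I >= threshold
  is_case <- !is.na(phenotype) & phenotype == "CASE"
  is_ctrl <- !is.na(phenotype) & phenotype == "CONTROL"
  pcase <- colMeans(carriers[is_case, , drop = FALSE], na.rm = TRUE)
  pctrl <- colMeans(carriers[is_ctrl, , drop = FALSE], na.rm = TRUE)
  list(
    carriers = carriers,
    proh = tibble(snp_id = profile$anchors$snp_id,
                  pROH_cases = as.numeric(pcase),
                  pROH_controls = as.numeric(pctrl))
  )
}

#' Merge significant anchors into regions
#'
#' Maximal runs of consecutive anchors (adjacent rows of the scan on the
#' same chromosome) with `-log10(p)` above the genome-wide threshold are
#' merged into regions spanning the first to the last anchor position.
#' Anchors with missing p-values break runs.
#'
#' @param scan A `scan_result` (or any tibble with `chromosome`,
#'   `position_bp`, `snp_id`, `minus_log10_p`).
#' @param threshold_log10p Genome-wide significance threshold on
#'   `-log10(p)` (default 8).
#' @return A tibble: `chromosome`, `start_bp`, `end_bp`, `start_snp`,
#'   `end_snp`, `n_anchors`, `peak_minus_log10_p`.
#' @export
significant_regions <- function(scan, threshold_log10p = 8) {
  hit <- !is.na(scan$minus_log10_p) & scan$minus_log10_p > threshold_log10p
  empty <- tibble(chromosome = character(), start_bp = integer(),
                  end_bp = integer(), start_snp = character(),
                  end_snp = character(), n_anchors = integer(),
                  peak_minus_log10_p = numeric())
  if (!any(hit)) return(empty)
  new_run <- hit & (!c(FALSE, hit[-length(hit)]) |
                      c(TRUE, scan$chromosome[-1] != scan$chromosome[-nrow(scan)]))
  run_id <- cumsum(new_run)
  run_id[!hit] <- NA
  idx <- split(which(hit), run_id[hit])
  purrr::map_dfr(idx, function(i) {
    tibble(chromosome = scan$chromosome[i[1L]],
           start_bp = scan$position_bp[i[1L]],
           end_bp = scan$position_bp[i[length(i)]],
           start_snp = scan$snp_id[i[1L]],
           end_snp = scan$snp_id[i[length(i)]],
           n_anchors = length(i),
           peak_minus_log10_p = max(scan$minus_log10_p[i]))
  })
}
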