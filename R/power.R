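#' @rdname estimate_power
#' @export
power_background_snps <- function(L, W, buffer_snps = 100) {
  as.integer(L + 2L * (2L * W + buffer_snps))
}

# Precomputed geometry for scanning one simulated map: windows, the anchors
# whose windows overlap the tract, and the tricube coefficient band matrices
# for the tract-center anchor and for the full overlapping set.
power_scan_context <- function(map, W, tract_start, tract_end) {
  windows <- build_windows(map, W)
  overlap <- windows$window_end >= tract_start & windows$window_start <= tract_end
  wo <- windows[overlap, , drop = FALSE]
  center_idx <- (tract_start + tract_end) %/% 2L
  wc <- windows[windows$anchor_idx == center_idx, , drop = FALSE]
  des_o <- tricube_design(map, wo)
  des_c <- tricube_design(map, wc)
  bo <- band_matrix(des_o$coef, wo, nrow(map))
  bc <- band_matrix(des_c$coef, wc, nrow(map))
  list(W = W, windows_overlap = wo, center_anchor = center_idx,
       K_overlap = bo, K_center = bc)
}

# -log10 p at each anchor of a precomputed band, complete-data fast path.
scan_band_logp <- function(S, band, is_case) {
  I <- clamp_unit(S[, band$lo:band$hi, drop = FALSE] %*% band$K)
  q <- clamp_unit(cpp_col_medians(I))
  K <- kl_distance(I, rep(q, each = nrow(I)))
  res <- cpp_ranksum_logp(K, is_case, TRUE)
  -res[, 1L] / log(10)
}

#' Detect the embedded tract in one simulated replicate
#'
#' Runs the homozygosity scan on a [simulate_cohort()] cohort and reports
#' whether the disease-associated tract is detected at the genome-wide
#' threshold. Under the default `"any_overlap"` rule detection means any
#' anchor whose window overlaps the tract attains
#' `-log10(p) > threshold_log10p`; under `"center_anchor"` only the anchor at
#' the tract center is tested. The tract-center anchor is always evaluated
#' first so that clearly detected replicates exit early; each anchor's test
#' does not depend on any other anchor, so the staging does not change the
#' result.
#'
#' @param cohort A `synthetic_cohort` (needs a defined tract).
#' @param W Window size in SNPs.
#' @param threshold_log10p Genome-wide threshold on `-log10(p)` (default 8).
#' @param rule Detection rule.
#' @param context Optional precomputed scan geometry (internal; used by
#'   [estimate_power()] to avoid rebuilding windows every replicate).
#' @return Logical scalar.
#' @export
detect_in_replicate <- function(cohort, W, threshold_log10p = 8,
                                rule = c("any_overlap", "center_anchor"),
                                context = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(cohort, "synthetic_cohort"))
  ts <- cohort$tract_start_idx
  te <- cohort$tract_end_idx
  if (is.null(context)) {
    context <- power_scan_context(cohort$map, W, ts, te)
  }
  is_case <- cohort$phenotype == "CASE"
  S <- geno_states(cohort)

  if (anyNA(S)) {
    # general path under missingness
    anchors <- if (rule == "center_anchor") context$center_anchor else
      context$windows_overlap$anchor_idx
    scan <- roh_scan(cohort, W, anchors = anchors)
    return(any(scan$minus_log10_p > threshold_log10p, na.rm = TRUE))
  }

  center_lp <- scan_band_logp(S, context$K_center, is_case)
  if (rule == "center_anchor") return(center_lp > threshold_log10p)
  if (isTRUE(center_lp > threshold_log10p)) return(TRUE)
  lp <- scan_band_logp(S, context$K_overlap, is_case)
  any(lp > threshold_log10p, na.rm = TRUE)
}

#' Estimate detection power of the homozygosity scan by simulation
#'
#' The power study: replicate cohorts are drawn with [simulate_cohort()] on a
#' tract-local background (the tract of `L` SNPs plus `2 W` SNPs and a
#' `buffer_snps` buffer on each side — detection under the fixed genome-wide
#' threshold depends only on windows overlapping the tract, so the local
#' background leaves the estimand unchanged while keeping the study
#' desk-scale), scanned at window size `W`, and power is the fraction of
#' replicates in which the tract is detected (see [detect_in_replicate()]).
#'
#' @param delta Fraction of cases carrying the tract.
#' @param L Tract length in SNPs.
#' @param epsilon Heterozygous-interference fraction inside the tract.
#' @param W Scan window size in SNPs.
#' @param n_cases,n_controls Group sizes (defaults 2000/3000).
#' @param n_replicates Number of simulation replicates (default 200; the
#'   binomial standard error is reported).
#' @param threshold_log10p Genome-wide threshold on `-log10(p)`.
#' @param spacing_bp,maf_law,missing_rate Passed to [cohort_sim_config()].
#' @param buffer_snps Extra background SNPs per side beyond `2 W`.
#' @param rule Detection rule, see [detect_in_replicate()].
#' @param seed Master seed from which independent per-replicate seeds are
#'   derived.
#' @param rep_seeds Explicit per-replicate seeds (overrides `seed`); used by
#'   [power_grid()] for common random numbers across grid cells.
#' @return A `power_estimate` tibble with one row: the design parameters,
#'   `power`, `se` and `n_replicates`. Per-replicate detection flags are kept
#'   in `attr(, "flags")`.
#' @export
estimate_power <- function(delta, L, epsilon, W,
                           n_cases = 2000, n_controls = 3000,
                           n_replicates = 200, threshold_log10p = 8,
                           spacing_bp = 3000, maf_law = maf_law_default(),
                           missing_rate = 0, buffer_snps = 100,
                           rule = c("any_overlap", "center_anchor"),
                           seed = NULL, rep_seeds = NULL) {
  rule <- match.arg(rule)
  stopifnot(n_replicates >= 1)
  rep_seeds <- rep_seeds %||% derive_seeds(n_replicates, seed)
  stopifnot(length(rep_seeds) == n_replicates)
  config <- cohort_sim_config(
    n_cases = n_cases, n_controls = n_controls,
    n_snps = power_background_snps(L, W, buffer_snps),
    spacing_bp = spacing_bp, maf_law = maf_law, L = L,
    delta = delta, epsilon = epsilon, missing_rate = missing_rate
  )
  ts <- (config$n_snps - L) %/% 2L + 1L
  map <- tibble(snp_id = paste0("snp", seq_len(config$n_snps)),
                chromosome = config$chromosome,
                position_bp = config$spacing_bp * seq_len(config$n_snps))
  context <- power_scan_context(map, W, ts, ts + L - 1L)

  flags <- vapply(seq_len(n_replicates), function(r) {
    cohort <- simulate_cohort(config, seed = rep_seeds[r])
    detect_in_replicate(cohort, W, threshold_log10p = threshold_log10p,
                        rule = rule, context = context)
  }, logical(1))

  power <- mean(flags)
  out <- tibble(
    delta = delta, L = as.integer(L), epsilon = epsilon, W = as.integer(W),
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    threshold_log10p = threshold_log10p,
    n_replicates = as.integer(n_replicates),
    power = power,
    se = sqrt(power * (1 - power) / n_replicates)
  )
  class(out) <- c("power_estimate", class(out))
  attr(out, "flags") <- flags
  attr(out, "rep_seeds") <- rep_seeds
  out
}

#' Power over a (delta, L, epsilon, W) grid
#'
#' Evaluates [estimate_power()] over the full Cartesian product of the
#' supplied parameter grids. All cells share the same per-replicate seeds
#' (common random numbers), which sharpens monotonicity comparisons across
#' cells.
#'
#' @param deltas,Ls,epsilons,Ws Parameter grids (non-empty).
#' @param ... Passed on to [estimate_power()].
#' @param n_replicates Replicates per cell.
#' @param seed Master seed for the shared per-replicate seeds.
#' @return A `power_grid` tibble, one row per cell.
#' @export
power_grid <- function(deltas, Ls, epsilons, Ws, ...,
                       n_replicates = 200, seed = NULL) {
  stopifnot(length(deltas) >= 1, length(Ls) >= 1,
            length(epsilons) >= 1, length(Ws) >= 1)
  rep_seeds <- derive_seeds(n_replicates, seed)
  cells <- tidyr::expand_grid(delta = deltas, L = Ls,
                              epsilon = epsilons, W = Ws)
  out <- purrr::pmap_dfr(cells, function(delta, L, epsilon, W) {
    estimate_power(delta = delta, L = L, epsilon = epsilon, W = W, ...,
                   n_replicates = n_replicates, rep_seeds = rep_seeds)
  })
  class(out) <- c("power_grid", class(out))
  out
}

#' @rdname estimate_power
#' @param x A `power_estimate`.
#' @param ... Unused.
#' @export
glance.power_estimate <- function(x, ...) {
  tibble(power = x$power, se = x$se, n_replicates = x$n_replicates)
}
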