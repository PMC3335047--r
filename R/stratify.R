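#' Principal components of the genotype matrix
#'
#' A plain genotype PCA for population-structure adjustment: genotypes are
#' coded additively (0/1/2 minor alleles), monomorphic SNPs dropped, each
#' SNP column centered and scaled by `sqrt(p(1-p))` with `p` the sample
#' allele frequency, missing entries set to the column mean (zero after
#' centering), and the top-`k` right-singular-vector scores returned.
#'
#' @param cohort A [roh_cohort()].
#' @param k Number of components (default 10).
#' @return A `genotype_pca` object: list with `scores` (tibble:
#'   `individual_id`, `PC1..PCk`), `sdev` (all singular values scaled by
#'   `1/sqrt(n-1)`) and `n_snps_used`.
#' @export
genotype_pca <- function(cohort, k = 10) {
  g <- cohort$genotypes
  n <- nrow(g)
  p_hat <- colMeans(g, na.rm = TRUE) / 2
  keep <- !is.na(p_hat) & p_hat > 0 & p_hat < 1
  g <- g[, keep, drop = FALSE]
  p_hat <- p_hat[keep]
  if (k >= min(n, ncol(g))) {
    stop("k must be smaller than min(n_individuals, n_polymorphic_snps)",
         call. = FALSE)
  }
  x <- sweep(g, 2L, 2 * p_hat, "-")
  x <- sweep(x, 2L, sqrt(p_hat * (1 - p_hat)), "/")
  x[is.na(x)] <- 0
  sv <- svd(x, nu = k, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(
    list(scores = tibble(individual_id = rownames(g), as_tibble(scores)),
         sdev = sv$d / sqrt(max(n - 1, 1)),
         n_snps_used = ncol(g)),
    class = "genotype_pca"
  )
}

#' @export
print.genotype_pca <- function(x, ...) {
  k <- ncol(x$scores) - 1L
  cat("<genotype_pca> ", nrow(x$scores), " individuals, ", k,
      " components (", x$n_snps_used, " SNPs)\n", sep = "")
  invisible(x)
}

#' @rdname genotype_pca
#' @param x A `genotype_pca`.
#' @param ... Unused.
#' @export
tidy.genotype_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -"individual_id",
                      names_to = "component", values_to = "score")
}

#' Stratification-adjusted association scan
#'
#' Per anchor, ordinary least squares of the homozygote intensity on an
#' intercept, case/control status (CASE = 1) and the leading principal
#' components, with a two-sided t-test on the status coefficient. With no
#' principal components this is algebraically the pooled-variance two-sample
#' t-test. P-values are computed in log space.
#'
#' @param profile An [homozygote_intensity()] result (or [kl_profile()]; the
#'   intensity is the regression response).
#' @param phenotype Optional status override.
#' @param pcs Principal-component scores: a [genotype_pca()] object, a
#'   numeric matrix, or `NULL` for an unadjusted (status-only) regression.
#' @return An `adjusted_scan_result` tibble: `anchor_idx`, `snp_id`,
#'   `chromosome`, `position_bp`, `estimate` (status coefficient), `se`,
#'   `statistic`, `minus_log10_p`. Anchors with a collinear design or
#'   missing intensities that break the shared fit are flagged `NA`.
#' @export
adjusted_scan <- function(profile, phenotype = NULL, pcs = NULL) {
  I <- profile$intensity
  n <- nrow(I)
  phenotype <- validate_phenotype(phenotype %||% profile$phenotype, n)
  check_two_groups(phenotype)
  status <- as.numeric(phenotype == "CASE")
  if (inherits(pcs, "genotype_pca")) {
    pcs <- as.matrix(pcs$scores[, -1L, drop = FALSE])
  }
  X <- cbind(`(Intercept)` = 1, status = status)
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    stopifnot(nrow(pcs) == n)
    X <- cbind(X, pcs)
  }
  p <- ncol(X)
  qrX <- qr(X)
  collinear_design <- qrX$rank < p

  est <- se <- tstat <- mlp <- rep(NA_real_, ncol(I))
  if (!collinear_design) {
    XtXinv <- chol2inv(qr.R(qrX))
    complete <- !colSums(is.na(I))
    if (any(complete)) {
      Ic <- I[, complete, drop = FALSE]
      B <- XtXinv %*% crossprod(X, Ic)
      resid <- Ic - X %*% B
      s2 <- colSums(resid^2) / (n - p)
      est[complete] <- B[2L, ]
      se[complete] <- sqrt(s2 * XtXinv[2L, 2L])
      tstat[complete] <- est[complete] / se[complete]
      logp <- pt(abs(tstat[complete]), df = n - p, lower.tail = FALSE,
                 log.p = TRUE) + log(2)
      mlp[complete] <- -logp / log(10)
    }
    for (j in which(!complete)) {
      ok <- !is.na(I[, j])
      if (sum(ok) <= p) next
      fit <- lm(I[ok, j] ~ X[ok, -1L, drop = FALSE])
      co <- summary(fit)$coefficients
      if (nrow(co) < 2L || is.na(co[2L, 2L])) next
      est[j] <- co[2L, 1L]; se[j] <- co[2L, 2L]; tstat[j] <- co[2L, 3L]
      mlp[j] <- -log10(co[2L, 4L])
    }
  }
  out <- tibble(
    anchor_idx = profile$anchors$anchor_idx,
    snp_id = profile$anchors$snp_id,
    chromosome = profile$anchors$chromosome,
    position_bp = profile$anchors$position_bp,
    estimate = est, se = se, statistic = tstat, minus_log10_p = mlp
  )
  class(out) <- c("adjusted_scan_result", class(out))
  attr(out, "n_pcs") <- if (is.null(pcs)) 0L else ncol(pcs)
  attr(out, "collinear_design") <- collinear_design
  out
}
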