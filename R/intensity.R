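#' Local-polynomial homozygote intensity for a single window
#'
#' Reference (scalar) implementation of the smoother: a degree-1 weighted
#' least-squares fit of the homozygous/heterozygous states (0/1) on physical
#' position, with tricube weights
#' \eqn{w_j = (1 - (d_j/d_{max})^3)^3}, \eqn{d_j = |pos_j - pos_{anchor}|},
#' evaluated at the anchor position and clamped to
#' \eqn{[\zeta, 1-\zeta]}, \eqn{\zeta = 10^{-6}}. Weights are computed from
#' the full window geometry; missing states are excluded from the fit (the
#' fitted curve stands in for them). Fewer than two non-missing states give
#' `NA`; a degenerate design (all positive weight at one position) falls back
#' to the tricube-weighted mean.
#'
#' @param states Numeric vector of member states (1 homozygous, 0
#'   heterozygous, `NA` missing).
#' @param positions Member positions in bp (same length).
#' @param anchor_position Position of the anchor SNP.
#' @return A single intensity in \eqn{[\zeta, 1-\zeta]}, or `NA`.
#' @examples
#' local_poly_intensity(c(1, 0, 1), c(100, 200, 300), 200)
#' @export
local_poly_intensity <- function(states, positions, anchor_position) {
  stopifnot(length(states) == length(positions))
  x <- as.numeric(positions) - as.numeric(anchor_position)
  dmax <- max(abs(x))
  if (dmax > 0) x <- x / dmax
  w <- if (dmax > 0) (1 - abs(x)^3)^3 else rep(1, length(x))
  keep <- !is.na(states)
  if (sum(keep) < 2L) return(NA_real_)
  w <- w[keep]; x <- x[keep]; s <- states[keep]
  sw <- sum(w); swx <- sum(w * x); swxx <- sum(w * x^2)
  D <- sw * swxx - swx^2
  fit <- if (D > 1e-12) {
    (swxx * sum(w * s) - swx * sum(w * x * s)) / D
  } else if (sw > 0) {
    sum(w * s) / sw
  } else {
    return(NA_real_)
  }
  clamp_unit(fit)
}

#' Per-individual homozygote intensity profile
#'
#' Applies the tricube-weighted local linear smoother of
#' [local_poly_intensity()] to every (individual, anchor) pair. Windows are
#' built with [build_windows()]; with complete data the fit reduces to one
#' matrix product of the state matrix with precomputed per-anchor coefficient
#' vectors, and under missingness the per-individual weighted sums are
#' assembled from masked matrix products, so both paths are vectorized and
#' agree with the scalar reference.
#'
#' @param cohort A [roh_cohort()].
#' @param W Window size in SNPs.
#' @param anchors Optional anchor indices (default: every SNP).
#' @param windows Optionally, precomputed [build_windows()] output for `map`
#'   and `W` (used by the power simulation to avoid rebuilding).
#' @return An `intensity_profile`: list with `intensity` (individuals x
#'   anchors matrix, `NA` where fewer than two states were observed),
#'   `anchors` (tibble as from [build_windows()], plus `n_excluded`, the
#'   count of individuals without a fittable window), `W` and `phenotype`.
#' @export
homozygote_intensity <- function(cohort, W, anchors = NULL, windows = NULL) {
  stopifnot(inherits(cohort, "roh_cohort"))
  if (is.null(windows)) {
    windows <- build_windows(cohort$map, W, anchors = anchors)
  } else if (!is.null(anchors)) {
    windows <- windows[match(anchors, windows$anchor_idx), , drop = FALSE]
  }
  des <- tricube_design(cohort$map, windows)
  S <- geno_states(cohort)
  n <- nrow(S)

  if (!anyNA(S)) {
    bm <- band_matrix(des$coef, windows, ncol(S))
    I <- S[, bm$lo:bm$hi, drop = FALSE] %*% bm$K
  } else {
    M <- 1 - is.na(S)           # observation mask
    S0 <- S; S0[is.na(S0)] <- 0
    kw <- band_matrix(des$Wt, windows, ncol(S))
    kwx <- band_matrix(des$Wt * des$X, windows, ncol(S))
    kwxx <- band_matrix(des$Wt * des$X^2, windows, ncol(S))
    kn <- band_matrix(des$mask + 0, windows, ncol(S))
    cols <- kw$lo:kw$hi
    Ms <- M[, cols, drop = FALSE]; S0s <- S0[, cols, drop = FALSE]
    sw <- Ms %*% kw$K
    swx <- Ms %*% kwx$K
    swxx <- Ms %*% kwxx$K
    sws <- S0s %*% kw$K
    swxs <- S0s %*% kwx$K
    nobs <- Ms %*% kn$K
    D <- sw * swxx - swx^2
    I <- (swxx * sws - swx * swxs) / D
    fallback <- D <= 1e-12 & sw > 0
    I[fallback] <- (sws / sw)[fallback]
    I[nobs < 2] <- NA_real_
  }
  I <- clamp_unit(I)
  dimnames(I) <- list(rownames(S), windows$snp_id)
  anchors_tb <- windows
  anchors_tb$n_excluded <- unname(colSums(is.na(I)))
  structure(
    list(intensity = I, anchors = anchors_tb, W = W,
         phenotype = cohort$phenotype),
    class = "intensity_profile"
  )
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat("<intensity_profile> ", nrow(x$intensity), " individuals x ",
      ncol(x$intensity), " anchors (W = ", x$W, ")\n", sep = "")
  invisible(x)
}

#' Signed Bernoulli Kullback-Leibler distance
#'
#' The Kullback-Leibler distance between Bernoulli distributions with success
#' probabilities `p` (an individual's homozygote intensity) and `q` (the
#' cohort reference),
#' \deqn{D = p \log(p/q) + (1-p) \log((1-p)/(1-q)),}
#' signed by `sign(p - q)` so that positive values mean excess homozygosity
#' relative to the reference. Zero exactly when `p == q`, and strictly
#' increasing in `p` for fixed `q`.
#'
#' @param p,q Probabilities strictly inside (0, 1); vectors recycle.
#' @return Signed distances.
#' @examples
#' kl_distance(0.9, 0.5)
#' kl_distance(0.1, 0.5)
#' @export
kl_distance <- function(p, q) {
  d <- p * (log(p) - log(q)) + (1 - p) * (log1p(-p) - log1p(-q))
  out <- sign(p - q) * d
  out[p == q] <- 0
  out
}

#' Pooled reference median intensity
#'
#' The per-anchor reference is the sample median homozygote intensity over
#' all individuals, cases and controls pooled (midpoint convention for even
#' counts), clamped inside (0, 1).
#'
#' @param intensities Numeric vector of intensities at one anchor.
#' @return The clamped median, `NA` if nothing is observed.
#' @export
reference_median <- function(intensities) {
  x <- intensities[!is.na(intensities)]
  if (length(x) == 0L) return(NA_real_)
  clamp_unit(median(x))
}

#' Signed Kullback-Leibler deviation profile
#'
#' Converts an intensity profile into per-(individual, anchor) signed
#' Kullback-Leibler deviations from the pooled per-anchor median intensity
#' (see [kl_distance()] and [reference_median()]).
#'
#' @param profile An [homozygote_intensity()] result.
#' @return A `kl_profile`: list with `kl` (matrix), `reference` (per-anchor
#'   median), plus the `intensity`, `anchors`, `W` and `phenotype` carried
#'   through.
#' @export
kl_profile <- function(profile) {
  stopifnot(inherits(profile, "intensity_profile"))
  q <- clamp_unit(cpp_col_medians(profile$intensity))
  K <- kl_distance(profile$intensity, rep(q, each = nrow(profile$intensity)))
  dimnames(K) <- dimnames(profile$intensity)
  structure(
    list(kl = K, reference = q, intensity = profile$intensity,
         anchors = profile$anchors, W = profile$W,
         phenotype = profile$phenotype),
    class = "kl_profile"
  )
}

#' @export
print.kl_profile <- function(x, ...) {
  cat("<kl_profile> ", nrow(x$kl), " individuals x ", ncol(x$kl),
      " anchors (W = ", x$W, ")\n", sep = "")
  invisible(x)
}

#' @rdname homozygote_intensity
#' @param x An `intensity_profile`.
#' @param ... Unused.
#' @export
tidy.intensity_profile <- function(x, ...) {
  tb <- as_tibble(x$intensity, .name_repair = "minimal")
  names(tb) <- x$anchors$snp_id
  tb$individual_id <- rownames(x$intensity)
  tb$status <- as.character(x$phenotype)
  tidyr::pivot_longer(tb, -c("individual_id", "status"),
                      names_to = "snp_id", values_to = "intensity")
}
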