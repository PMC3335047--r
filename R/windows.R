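#' Build sliding SNP windows
#'
#' For every SNP (the anchor) a window of the `W` SNPs nearest to it in
#' physical distance on the same chromosome is constructed (the anchor plus
#' its `W - 1` nearest neighbours). Because the map is position-sorted the
#' members always form a contiguous index interval. Near chromosome ends the
#' window is asymmetric, taking the `W` nearest available SNPs; equidistant
#' candidates are resolved toward the lower index. Chromosomes with fewer
#' than `W` SNPs yield truncated windows which are flagged.
#'
#' @param map A SNP map (see [roh_cohort()]), sorted by position within
#'   chromosome.
#' @param W Window size in SNPs (>= 2; anchors on single-SNP chromosomes get
#'   a flagged window of size 1).
#' @param anchors Optional integer vector of anchor indices (rows of `map`);
#'   default all SNPs (stride 1).
#' @return A tibble with one row per anchor: `anchor_idx`, `snp_id`,
#'   `chromosome`, `position_bp`, `window_start`, `window_end` (global map
#'   row indices of the contiguous member interval), `window_size`,
#'   `truncated`.
#' @examples
#' map <- tibble::tibble(snp_id = paste0("s", 1:5), chromosome = "1",
#'                       position_bp = c(10L, 20L, 30L, 40L, 50L))
#' build_windows(map, W = 3)
#' @export
build_windows <- function(map, W, anchors = NULL) {
  map <- validate_snp_map(map)
  stopifnot(W >= 2)
  m <- nrow(map)
  anchors <- as.integer(anchors %||% seq_len(m))
  stopifnot(all(anchors >= 1L), all(anchors <= m))
  chrom <- map$chromosome
  pos <- as.numeric(map$position_bp)
  # chromosome extents (map is grouped by chromosome, sorted within)
  chr_first <- which(!duplicated(chrom))
  chr_last <- c(chr_first[-1L] - 1L, m)
  first_of <- chr_first[match(chrom, chrom[chr_first])]
  last_of <- chr_last[match(chrom, chrom[chr_first])]

  ws <- integer(length(anchors))
  we <- integer(length(anchors))
  for (k in seq_along(anchors)) {
    a <- anchors[k]
    lo <- a; hi <- a
    lo_min <- first_of[a]; hi_max <- last_of[a]
    target <- min(W, hi_max - lo_min + 1L)
    while (hi - lo + 1L < target) {
      left_ok <- lo > lo_min
      right_ok <- hi < hi_max
      if (left_ok && right_ok) {
        dl <- pos[a] - pos[lo - 1L]
        dr <- pos[hi + 1L] - pos[a]
        if (dl <= dr) lo <- lo - 1L else hi <- hi + 1L # tie: lower index
      } else if (left_ok) {
        lo <- lo - 1L
      } else {
        hi <- hi + 1L
      }
    }
    ws[k] <- lo; we[k] <- hi
  }
  tibble(
    anchor_idx = anchors,
    snp_id = map$snp_id[anchors],
    chromosome = chrom[anchors],
    position_bp = map$position_bp[anchors],
    window_start = ws,
    window_end = we,
    window_size = we - ws + 1L,
    truncated = (we - ws + 1L) < W
  )
}

# Tricube local-linear coefficient matrices for a set of windows.
#
# For anchor a with member positions x_j (centered at the anchor and scaled
# by the maximum in-window distance d_max for conditioning), tricube weights
# w_j = (1 - |x_j|^3)^3 (w = 1 when d_max = 0). The degree-1 weighted
# least-squares fit evaluated at the anchor is linear in the member states:
#   I_a = sum_j c_j s_j,  c_j = w_j (Swxx - x_j Swx) / D,
#   Swx = sum w x, Swxx = sum w x^2, D = Sw Swxx - Swx^2.
# Returns padded (Wmax x A) matrices used by both the complete-data path
# (coef) and the missing-data path (w, wx, wxx and the position design).
tricube_design <- function(map, windows) {
  pos <- as.numeric(map$position_bp)
  A <- nrow(windows)
  Wmax <- max(windows$window_size)
  X <- matrix(0, Wmax, A)
  Wt <- matrix(0, Wmax, A)
  mask <- matrix(FALSE, Wmax, A)
  for (k in seq_len(A)) {
    idx <- windows$window_start[k]:windows$window_end[k]
    x <- pos[idx] - pos[windows$anchor_idx[k]]
    dmax <- max(abs(x))
    if (dmax > 0) x <- x / dmax
    w <- if (dmax > 0) (1 - abs(x)^3)^3 else rep(1, length(x))
    len <- length(idx)
    X[seq_len(len), k] <- x
    Wt[seq_len(len), k] <- w
    mask[seq_len(len), k] <- TRUE
  }
  sw <- colSums(Wt)
  swx <- colSums(Wt * X)
  swxx <- colSums(Wt * X * X)
  D <- sw * swxx - swx^2
  coef <- Wt * (rep(swxx, each = Wmax) - X * rep(swx, each = Wmax))
  ok <- D > 1e-12
  coef[, ok] <- sweep(coef[, ok, drop = FALSE], 2L, D[ok], "/")
  # degenerate design (e.g. all positive weight at one position):
  # fall back to the tricube-weighted mean
  if (any(!ok)) {
    coef[, !ok] <- sweep(Wt[, !ok, drop = FALSE], 2L, sw[!ok], "/")
  }
  list(X = X, Wt = Wt, mask = mask, coef = coef, degenerate = !ok)
}

# Dense band matrix K (m x A) with K[start_a:end_a, a] = vals[1:len_a, a],
# restricted to the column range actually touched, returning the row offset.
band_matrix <- function(vals, windows, m) {
  lo <- min(windows$window_start)
  hi <- max(windows$window_end)
  K <- matrix(0, hi - lo + 1L, nrow(windows))
  for (k in seq_len(nrow(windows))) {
    len <- windows$window_size[k]
    rows <- (windows$window_start[k]:windows$window_end[k]) - lo + 1L
    K[rows, k] <- vals[seq_len(len), k]
  }
  list(K = K, lo = lo, hi = hi)
}
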