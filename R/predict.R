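#' Cross-validated discriminant-analysis accuracy
#'
#' Predicts case/control status from homozygote-intensity features with a
#' linear (or quadratic) discriminant classifier under stratified k-fold
#' cross-validation: folds preserve the class proportions, the classifier is
#' trained with empirical class priors and equal misclassification costs,
#' and accuracy is the fraction of correct held-out predictions. The mean
#' accuracy equals the fold accuracies weighted by fold size. Folds with
#' zero within-class variance in training fall back to the prior-majority
#' classifier.
#'
#' @param features Numeric vector (one feature) or matrix (individuals x
#'   features).
#' @param phenotype Per-individual `CASE`/`CONTROL` labels.
#' @param k_folds Number of folds (default 10).
#' @param seed Optional integer seed for the fold shuffle.
#' @param method `"lda"` or `"qda"`.
#' @return A `cv_prediction`: list with `mean_accuracy`, `folds` (tibble:
#'   `fold`, `n`, `accuracy`), `assignment` (per-individual fold) and
#'   `method`.
#' @export
lda_cv_accuracy <- function(features, phenotype, k_folds = 10, seed = NULL,
                            method = c("lda", "qda")) {
  method <- match.arg(method)
  features <- as.matrix(features)
  phenotype <- validate_phenotype(phenotype, nrow(features))
  check_two_groups(phenotype)
  keep <- complete.cases(features) & !is.na(phenotype)
  features <- features[keep, , drop = FALSE]
  phenotype <- droplevels(phenotype[keep])
  n <- nrow(features)
  if (!is.null(seed)) set.seed(seed)

  # stratified folds: shuffle within class, deal round-robin
  assignment <- integer(n)
  for (cl in levels(phenotype)) {
    idx <- sample(which(phenotype == cl))
    assignment[idx] <- rep_len(seq_len(k_folds), length(idx))
  }
  majority <- levels(phenotype)[which.max(table(phenotype))]

  correct <- integer(k_folds)
  sizes <- integer(k_folds)
  for (f in seq_len(k_folds)) {
    test <- assignment == f
    tr_x <- features[!test, , drop = FALSE]
    tr_y <- phenotype[!test]
    degenerate <- any(vapply(levels(tr_y), function(cl) {
      v <- apply(tr_x[tr_y == cl, , drop = FALSE], 2L, var)
      any(!is.finite(v)) || any(v == 0)
    }, logical(1)))
    pred <- if (degenerate) {
      rep(majority, sum(test))
    } else {
      tryCatch({
        fit <- if (method == "lda") MASS::lda(tr_x, grouping = tr_y) else
          MASS::qda(tr_x, grouping = tr_y)
        as.character(stats::predict(fit, features[test, , drop = FALSE])$class)
      }, error = function(e) rep(majority, sum(test)))
    }
    correct[f] <- sum(pred == as.character(phenotype[test]))
    sizes[f] <- sum(test)
  }
  structure(
    list(mean_accuracy = sum(correct) / n,
         folds = tibble(fold = seq_len(k_folds), n = sizes,
                        accuracy = correct / pmax(sizes, 1L)),
         assignment = assignment, method = method),
    class = "cv_prediction"
  )
}

#' @export
print.cv_prediction <- function(x, ...) {
  cat(sprintf("<cv_prediction> %s, %d folds, mean accuracy %.4f\n",
              x$method, nrow(x$folds), x$mean_accuracy))
  invisible(x)
}

#' @rdname lda_cv_accuracy
#' @param x A `cv_prediction`.
#' @param ... Unused.
#' @export
tidy.cv_prediction <- function(x, ...) x$folds

#' @rdname lda_cv_accuracy
#' @export
glance.cv_prediction <- function(x, ...) {
  tibble(mean_accuracy = x$mean_accuracy, k_folds = nrow(x$folds),
         method = x$method)
}

#' Per-anchor cross-validated prediction accuracy
#'
#' Runs [lda_cv_accuracy()] at every anchor of an intensity profile, using
#' the scalar homozygote intensity at the anchor as the feature (set
#' `features = "window"` to use all member-anchor intensities jointly).
#'
#' @param profile An [homozygote_intensity()] result.
#' @param phenotype Optional status override.
#' @param anchors Anchor snp_ids to evaluate (default all in the profile).
#' @param features `"anchor"` (scalar intensity, default) or `"window"` (the
#'   full intensity vector across the profile's anchors, evaluated once).
#' @inheritParams lda_cv_accuracy
#' @return A `cv_scan` tibble: `snp_id`, `position_bp`, `mean_accuracy`.
#' @export
predict_status_cv <- function(profile, phenotype = NULL, anchors = NULL,
                              k_folds = 10, seed = NULL,
                              method = c("lda", "qda"),
                              features = c("anchor", "window")) {
  method <- match.arg(method)
  features <- match.arg(features)
  phenotype <- validate_phenotype(phenotype %||% profile$phenotype,
                                  nrow(profile$intensity))
  ids <- anchors %||% profile$anchors$snp_id
  cols <- match(ids, profile$anchors$snp_id)
  stopifnot(!anyNA(cols))
  if (features == "window") {
    cv <- lda_cv_accuracy(profile$intensity, phenotype, k_folds = k_folds,
                          seed = seed, method = method)
    out <- tibble(snp_id = NA_character_, position_bp = NA_integer_,
                  mean_accuracy = cv$mean_accuracy)
  } else {
    acc <- vapply(cols, function(j) {
      lda_cv_accuracy(profile$intensity[, j], phenotype, k_folds = k_folds,
                      seed = seed, method = method)$mean_accuracy
    }, numeric(1))
    out <- tibble(snp_id = ids,
                  position_bp = profile$anchors$position_bp[cols],
                  mean_accuracy = acc)
  }
  class(out) <- c("cv_scan", class(out))
  out
}

#' Anchor with the best cross-validated accuracy
#'
#' @param results A `cv_scan` tibble (see [predict_status_cv()]).
#' @return The row of `results` with maximal mean accuracy; ties are broken
#'   toward the smaller position.
#' @export
best_anchor <- function(results) {
  stopifnot(nrow(results) >= 1)
  ord <- order(-results$mean_accuracy, results$position_bp)
  results[ord[1L], ]
}

#' ROH-carrying category table
#'
#' Cross-classifies individuals by the presence/absence of an ROH at `k` tag
#' anchors: each of the `2^k` indicator vectors is a category, summarised by
#' its within-group proportions. Categories whose case proportion exceeds
#' `min_proportion` are flagged for reporting, and a category is a risk
#' category when its case proportion exceeds its control proportion.
#'
#' @param carriers Logical individuals x anchors matrix of carrier calls
#'   (column names are the tag anchor ids), `k <= 16`.
#' @param phenotype Per-individual `CASE`/`CONTROL` labels.
#' @param min_proportion Reporting threshold on the case proportion
#'   (default 0.02).
#' @return A `category_summary` tibble: `category` (e.g. `"(1,0,0)"`), one
#'   indicator column per anchor, `pROH_cases`, `pROH_controls`, `risk`,
#'   `reported`. Proportions within each group sum to 1 over all categories.
#' @export
category_table <- function(carriers, phenotype, min_proportion = 0.02) {
  carriers <- as.matrix(carriers)
  k <- ncol(carriers)
  stopifnot(k >= 1, k <= 16)
  phenotype <- validate_phenotype(phenotype, nrow(carriers))
  check_two_groups(phenotype)
  code <- as.integer((carriers + 0) %*% 2^(seq_len(k) - 1L))
  lev <- 0:(2^k - 1L)
  fcode <- factor(code, levels = lev)
  p_case <- prop.table(table(fcode[phenotype == "CASE"]))
  p_ctrl <- prop.table(table(fcode[phenotype == "CONTROL"]))
  ind <- matrix(0L, length(lev), k)
  for (j in seq_len(k)) ind[, j] <- as.integer(bitwAnd(lev, 2^(j - 1L)) > 0)
  colnames(ind) <- colnames(carriers) %||% paste0("anchor", seq_len(k))
  out <- tibble(
    category = apply(ind, 1L, function(r) paste0("(", paste(r, collapse = ","), ")")),
    as_tibble(ind),
    pROH_cases = as.numeric(p_case),
    pROH_controls = as.numeric(p_ctrl)
  )
  out$risk <- out$pROH_cases > out$pROH_controls
  out$reported <- out$pROH_cases > min_proportion
  class(out) <- c("category_summary", class(out))
  out
}

#' Select tag anchors from carrier patterns
#'
#' Partitions contiguous anchors into maximal groups whose case-carrier sets
#' agree (pairwise Jaccard overlap above `jaccard_threshold`; two empty sets
#' count as identical), and emits one representative tag anchor per group:
#' the anchor with maximal case carrier proportion, ties broken toward the
#' smaller position.
#'
#' @param carriers Logical individuals x anchors matrix of carrier calls at
#'   contiguous anchors (columns in map order).
#' @param phenotype Per-individual `CASE`/`CONTROL` labels.
#' @param positions Anchor positions in bp (defaults to column order).
#' @param jaccard_threshold Minimum pairwise Jaccard overlap within a group
#'   (default 0.8).
#' @return A tibble: `group`, `anchor` (column index), `snp_id` (column
#'   name), `position_bp`, `pROH_cases`, `tag` (logical).
#' @export
select_tag_anchors <- function(carriers, phenotype, positions = NULL,
                               jaccard_threshold = 0.8) {
  carriers <- as.matrix(carriers)
  phenotype <- validate_phenotype(phenotype, nrow(carriers))
  A <- ncol(carriers)
  positions <- positions %||% seq_len(A)
  case_sets <- lapply(seq_len(A), function(j) {
    which(!is.na(carriers[, j]) & carriers[, j] & phenotype == "CASE")
  })
  jaccard <- function(a, b) {
    if (length(a) == 0L && length(b) == 0L) return(1)
    length(intersect(a, b)) / length(union(a, b))
  }
  group <- integer(A)
  g <- 1L
  members <- 1L
  group[1L] <- 1L
  for (j in seq_len(A)[-1L]) {
    ok <- all(vapply(members, function(m) {
      jaccard(case_sets[[j]], case_sets[[m]]) > jaccard_threshold
    }, logical(1)))
    if (ok) {
      members <- c(members, j)
    } else {
      g <- g + 1L
      members <- j
    }
    group[j] <- g
  }
  n_case <- sum(phenotype == "CASE", na.rm = TRUE)
  proh <- vapply(case_sets, length, integer(1)) / n_case
  out <- tibble(
    group = group,
    anchor = seq_len(A),
    snp_id = colnames(carriers) %||% paste0("anchor", seq_len(A)),
    position_bp = positions,
    pROH_cases = proh
  )
  out$tag <- FALSE
  for (gi in unique(group)) {
    rows <- which(group == gi)
    ord <- rows[order(-proh[rows], positions[rows])]
    out$tag[ord[1L]] <- TRUE
  }
  out
}
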