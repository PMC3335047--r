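#' Assemble a case-control genotype cohort
#'
#' The central container of the package: an individuals-by-SNPs matrix of
#' biallelic genotype calls, a SNP map with physical positions, and an
#' optional case/control phenotype. Genotypes are coded allele-agnostically
#' as the count of "B" alleles: `0` = AA, `1` = AB, `2` = BB, `NA` = missing.
#'
#' @param genotypes Integer matrix (individuals x SNPs) with values in
#'   `{0, 1, 2, NA}`. Character matrices of `"AA"/"AB"/"BB"` are accepted and
#'   recoded. Row names, if present, are used as individual ids.
#' @param map Data frame with columns `snp_id`, `chromosome`, `position_bp`;
#'   one row per genotype column, positions strictly increasing within each
#'   chromosome.
#' @param phenotype Optional per-individual status: factor or character with
#'   levels `"CASE"`/`"CONTROL"` (`NA` = unknown).
#'
#' @return An object of class `roh_cohort`: a list with elements `genotypes`,
#'   `map` (tibble) and `phenotype` (factor).
#' @examples
#' map <- tibble::tibble(snp_id = c("s1", "s2"), chromosome = "1",
#'                       position_bp = c(1000L, 2000L))
#' g <- matrix(c(0L, 1L, 2L, NA), 2, 2)
#' roh_cohort(g, map, c("CASE", "CONTROL"))
#' @export
roh_cohort <- function(genotypes, map, phenotype = NULL) {
  if (is.character(genotypes)) {
    dm <- dim(genotypes)
    genotypes <- match(genotypes, c("AA", "AB", "BB")) - 1L
    dim(genotypes) <- dm
  }
  if (!is.matrix(genotypes)) stop("`genotypes` must be a matrix", call. = FALSE)
  storage.mode(genotypes) <- "integer"
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("genotype calls must be 0 (AA), 1 (AB), 2 (BB) or NA", call. = FALSE)
  }
  map <- validate_snp_map(map)
  if (nrow(map) != ncol(genotypes)) {
    stop("map has ", nrow(map), " SNPs but genotypes has ", ncol(genotypes),
         " columns", call. = FALSE)
  }
  colnames(genotypes) <- map$snp_id
  if (is.null(rownames(genotypes))) {
    rownames(genotypes) <- paste0("ind", seq_len(nrow(genotypes)))
  }
  phenotype <- validate_phenotype(phenotype, nrow(genotypes))
  structure(
    list(genotypes = genotypes, map = map, phenotype = phenotype),
    class = "roh_cohort"
  )
}

validate_snp_map <- function(map) {
  map <- as_tibble(map)
  need <- c("snp_id", "chromosome", "position_bp")
  if (!all(need %in% names(map))) {
    stop("map must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  map$snp_id <- as.character(map$snp_id)
  map$chromosome <- as.character(map$chromosome)
  map$position_bp <- as.integer(map$position_bp)
  if (anyDuplicated(map$snp_id)) stop("snp_ids must be unique", call. = FALSE)
  if (any(map$position_bp <= 0L)) {
    stop("positions must be positive 1-based coordinates", call. = FALSE)
  }
  ok <- unlist(lapply(split(map$position_bp, factor(map$chromosome,
                                                    unique(map$chromosome))),
                      function(p) all(diff(p) > 0)))
  if (!all(ok)) {
    stop("positions must be strictly increasing within each chromosome",
         call. = FALSE)
  }
  map
}

validate_phenotype <- function(phenotype, n) {
  if (is.null(phenotype)) {
    return(factor(rep(NA_character_, n), levels = c("CASE", "CONTROL")))
  }
  phenotype <- factor(as.character(phenotype), levels = c("CASE", "CONTROL"))
  if (length(phenotype) != n) {
    stop("phenotype length must equal the number of individuals", call. = FALSE)
  }
  phenotype
}

check_two_groups <- function(phenotype) {
  tab <- table(phenotype)
  if (any(is.na(phenotype)) || length(tab) < 2 || any(tab == 0)) {
    stop("association tests need every individual labelled and both CASE ",
         "and CONTROL groups non-empty", call. = FALSE)
  }
  invisible(phenotype)
}

#' Homozygous/heterozygous state of a genotype call
#'
#' Maps calls to the binary response used by the local smoother: homozygous
#' (AA or BB) to 1, heterozygous (AB) to 0, missing to `NA`. The mapping is
#' invariant under relabelling of the two alleles.
#'
#' @param call Genotype calls: integer `0/1/2` codes or `"AA"/"AB"/"BB"`
#'   strings; vectors and matrices supported.
#' @return Numeric of the same shape with values 1 (homozygous), 0
#'   (heterozygous) or `NA`.
#' @examples
#' homozygosity_state(c("AA", "AB", "BB", NA))
#' @export
homozygosity_state <- function(call) {
  if (is.character(call)) {
    dm <- dim(call)
    call <- match(call, c("AA", "AB", "BB")) - 1L
    dim(call) <- dm
  }
  out <- (call != 1L) + 0
  out
}

# Numeric 0/1/NA state matrix of a cohort.
geno_states <- function(cohort) {
  homozygosity_state(cohort$genotypes)
}

genotype_labels <- function(genotypes) {
  lab <- c("AA", "AB", "BB")[genotypes + 1L]
  dim(lab) <- dim(genotypes)
  dimnames(lab) <- dimnames(genotypes)
  lab
}

#' @export
print.roh_cohort <- function(x, ...) {
  tab <- table(x$phenotype, useNA = "ifany")
  cat("<roh_cohort> ", nrow(x$genotypes), " individuals x ",
      ncol(x$genotypes), " SNPs on ",
      length(unique(x$map$chromosome)), " chromosome(s)\n", sep = "")
  cat("  phenotype: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  NextMethod()
  cat("  embedded tract: SNPs ", x$tract_start_idx, "-", x$tract_end_idx,
      " (", x$tract_end_idx - x$tract_start_idx + 1L, " SNPs), ",
      sum(x$carrier_mask), " carriers\n", sep = "")
  invisible(x)
}
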