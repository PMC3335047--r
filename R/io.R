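#' Read a PLINK text pedigree file pair
#'
#' Parses a whitespace-delimited `.ped`/`.map` pair into a [roh_cohort()].
#' The `.map` file must have four columns (chromosome, snp id, genetic
#' distance, bp position); the `.ped` file six leading columns (family,
#' individual, father, mother, sex, phenotype) followed by two allele columns
#' per SNP. Phenotypes follow the PLINK convention: 1 = control, 2 = case,
#' 0 or -9 = unknown. Genotypes are recoded against the (at most two) alleles
#' observed at each SNP; `0` alleles and any non-biallelic token make the call
#' missing. SNPs are reordered to ascending (chromosome, bp) with genotype
#' columns permuted identically.
#'
#' @param ped_path,map_path Paths to the `.ped` and `.map` files.
#' @return A [roh_cohort()]; the per-SNP allele labels observed are kept in
#'   `attr(, "alleles")` (a two-column matrix, `NA` where unobserved).
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("no such file: ", ped_path, call. = FALSE)
  if (!file.exists(map_path)) stop("no such file: ", map_path, call. = FALSE)
  map_raw <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                        col.names = c("chromosome", "snp_id", "cm", "position_bp"))
  m <- nrow(map_raw)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  toks <- strsplit(trimws(lines), "[ \t]+")
  expected <- 6L + 2L * m
  ids <- character(n)
  phen <- character(n)
  a1 <- matrix(NA_character_, n, m)
  a2 <- matrix(NA_character_, n, m)
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (length(tk) != expected) {
      stop(".ped line ", i, " has ", length(tk), " fields, expected ",
           expected, call. = FALSE)
    }
    ids[i] <- tk[2L]
    phen[i] <- tk[6L]
    al <- tk[-(1:6)]
    a1[i, ] <- al[seq(1L, 2L * m, by = 2L)]
    a2[i, ] <- al[seq(2L, 2L * m, by = 2L)]
  }
  a1[a1 == "0"] <- NA_character_
  a2[a2 == "0"] <- NA_character_
  # half-calls (one known allele) are treated as missing
  half <- xor(is.na(a1), is.na(a2))
  a1[half] <- NA_character_
  a2[half] <- NA_character_

  genotypes <- matrix(NA_integer_, n, m)
  alleles <- matrix(NA_character_, m, 2L)
  for (j in seq_len(m)) {
    obs <- sort(unique(c(a1[, j], a2[, j])))
    obs <- obs[!is.na(obs)]
    if (length(obs) > 2L) {
      stop("SNP ", map_raw$snp_id[j], " has ", length(obs),
           " alleles; only biallelic SNPs are supported", call. = FALSE)
    }
    alleles[j, seq_along(obs)] <- obs
    if (length(obs) == 0L) next
    b <- obs[length(obs)] # B = last allele alphabetically (arbitrary, consistent)
    genotypes[, j] <- (a1[, j] == b) + (a2[, j] == b)
  }

  phenotype <- rep(NA_character_, n)
  phenotype[phen == "1"] <- "CONTROL"
  phenotype[phen == "2"] <- "CASE"
  if (!all(phen %in% c("0", "-9", "1", "2"))) {
    warning("unrecognised phenotype codes treated as unknown")
  }

  map <- tibble(snp_id = as.character(map_raw$snp_id),
                chromosome = as.character(map_raw$chromosome),
                position_bp = as.integer(map_raw$position_bp))
  ord <- order(factor(map$chromosome, unique(map$chromosome)), map$position_bp)
  map <- map[ord, ]
  genotypes <- genotypes[, ord, drop = FALSE]
  alleles <- alleles[ord, , drop = FALSE]
  rownames(genotypes) <- ids
  out <- roh_cohort(genotypes, map, phenotype)
  attr(out, "alleles") <- alleles
  out
}

#' Write a cohort as a PLINK text pedigree file pair
#'
#' Inverse of [read_plink_text()]. Allele labels default to `"A"`/`"B"`;
#' missing calls are written as `0 0`, unknown phenotypes as `0`.
#'
#' @param cohort A [roh_cohort()].
#' @param ped_path,map_path Output paths.
#' @return Invisibly, the cohort.
#' @export
write_plink_text <- function(cohort, ped_path, map_path) {
  map <- cohort$map
  write.table(
    data.frame(map$chromosome, map$snp_id, 0, map$position_bp),
    map_path, quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE
  )
  g <- cohort$genotypes
  n <- nrow(g); m <- ncol(g)
  a1 <- matrix("A", n, m); a2 <- matrix("A", n, m)
  a1[g == 2L] <- "B"; a2[g >= 1L] <- "B"
  a1[is.na(g)] <- "0"; a2[is.na(g)] <- "0"
  phen <- c(CASE = "2", CONTROL = "1")[as.character(cohort$phenotype)]
  phen[is.na(phen)] <- "0"
  body <- matrix("", n, 2L * m)
  body[, seq(1L, 2L * m, 2L)] <- a1
  body[, seq(2L, 2L * m, 2L)] <- a2
  lead <- cbind("FAM", rownames(g), "0", "0", "0", phen)
  writeLines(apply(cbind(lead, body), 1L, paste, collapse = " "), ped_path)
  invisible(cohort)
}

#' Read or write a genotype TSV
#'
#' A simple tab-delimited dialect: one row per individual with columns
#' `individual_id`, `status` (`CASE`/`CONTROL`/`NA`) and one column per SNP
#' holding `AA`/`AB`/`BB`/`NA`. Positions are not part of the format, so the
#' reader takes an optional map; without one SNPs are placed on chromosome
#' `"1"` at 1 kb spacing.
#'
#' @param path File path.
#' @param map Optional SNP map matching the genotype columns.
#' @return `read_genotype_tsv()` returns a [roh_cohort()];
#'   `write_genotype_tsv()` invisibly returns the cohort.
#' @export
read_genotype_tsv <- function(path, map = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, na.strings = c("NA", ""))
  snp_cols <- setdiff(names(df), c("individual_id", "status"))
  g <- as.matrix(df[, snp_cols, drop = FALSE])
  rownames(g) <- df$individual_id
  if (is.null(map)) {
    map <- tibble(snp_id = snp_cols, chromosome = "1",
                  position_bp = 1000L * seq_along(snp_cols))
  }
  roh_cohort(g, map, df$status)
}

#' @rdname read_genotype_tsv
#' @param cohort A [roh_cohort()].
#' @export
write_genotype_tsv <- function(cohort, path) {
  lab <- genotype_labels(cohort$genotypes)
  df <- data.frame(individual_id = rownames(cohort$genotypes),
                   status = as.character(cohort$phenotype),
                   lab, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE,
              na = "NA")
  invisible(cohort)
}

#' Write regions as a BED file
#'
#' Internal coordinates are 1-based inclusive (as positions are printed in
#' genotype maps); on disk BED uses 0-based half-open coordinates, so
#' `start_bp - 1` and `end_bp` are written.
#'
#' @param regions Data frame with columns `chromosome`, `start_bp`, `end_bp`
#'   (1-based inclusive).
#' @param path Output path.
#' @return Invisibly, the path.
#' @examples
#' \dontrun{
#' write_bed_regions(
#'   tibble::tibble(chromosome = "6",
#'                  start_bp = 32451664, end_bp = 32846093),
#'   "regions.bed"
#' )
#' }
#' @export
write_bed_regions <- function(regions, path) {
  regions <- as_tibble(regions)
  if (nrow(regions) && any(regions$end_bp < regions$start_bp)) {
    stop("region end_bp before start_bp", call. = FALSE)
  }
  if (nrow(regions) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%s\t%s", regions$chromosome,
                   format(regions$start_bp - 1, scientific = FALSE, trim = TRUE),
                   format(regions$end_bp, scientific = FALSE, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}
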