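# Small in-code fixtures shared across test files.

toy_map <- function(m, spacing = 100L, chromosome = "1") {
  tibble::tibble(
    snp_id = paste0("s", seq_len(m)),
    chromosome = chromosome,
    position_bp = spacing * seq_len(m)
  )
}

toy_cohort <- function(genotypes, phenotype = NULL, spacing = 100L) {
  roh_cohort(genotypes, toy_map(ncol(genotypes), spacing), phenotype)
}

# Independent scalar oracle for the tricube local-linear fit: generic WLS via
# lm.wfit on the raw design, fitted value at the anchor position.
wls_oracle <- function(states, positions, anchor_position) {
  keep <- !is.na(states)
  x <- positions - anchor_position
  d <- abs(x)
  dmax <- max(d)
  w <- if (dmax > 0) (1 - (d / dmax)^3)^3 else rep(1, length(d))
  fit <- stats::lm.wfit(cbind(1, x[keep]), states[keep], w[keep])
  unname(fit$coefficients[1])
}

# Independent exact one-sided rank-sum oracle: enumerate all case-assignments.
enumeration_oracle <- function(cases, controls) {
  n1 <- length(cases)
  r <- rank(c(cases, controls))
  w_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(r), n1)
  wdist <- colSums(matrix(r[combs], nrow = n1))
  mean(wdist >= w_obs - 1e-9)
}
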