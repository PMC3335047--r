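test_that("PC1 separates two diverged subpopulations", {
  sils <- vapply(1:20, function(s) {
    co <- simulate_stratified_cohort(n_per_pop = c(60, 60), n_snps = 300,
                                     fst = 0.15, seed = s)
    pca <- genotype_pca(co, k = 2)
    pc1 <- pca$scores$PC1
    sil <- cluster::silhouette(as.integer(co$population),
                               stats::dist(pc1))
    mean(sil[, "sil_width"])
  }, numeric(1))
  expect_gt(min(sils), 0.5)
})

test_that("a homogeneous population has no outlier component", {
  for (s in 1:3) {
    cfg <- cohort_sim_config(n_cases = 60, n_controls = 60, n_snps = 400,
                             L = 10, delta = 0)
    co <- simulate_cohort(cfg, seed = 300 + s)
    pca <- genotype_pca(co, k = 20)
    top <- pca$sdev[1:20]^2
    expect_lt(max(top), 3 * mean(top))
  }
})

test_that("duplicating every individual leaves PC scores pairwise equal", {
  cfg <- cohort_sim_config(n_cases = 25, n_controls = 25, n_snps = 120,
                           L = 10, delta = 0)
  co <- simulate_cohort(cfg, seed = 17)
  g2 <- rbind(co$genotypes, co$genotypes)
  rownames(g2) <- paste0("i", seq_len(nrow(g2)))
  co2 <- roh_cohort(g2, co$map, rep(as.character(co$phenotype), 2))
  pca <- genotype_pca(co2, k = 3)
  s <- as.matrix(pca$scores[, -1])
  expect_equal(s[1:50, ], s[51:100, ], ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("k bounds are enforced", {
  cfg <- cohort_sim_config(n_cases = 10, n_controls = 10, n_snps = 50,
                           L = 10, delta = 0)
  co <- simulate_cohort(cfg, seed = 1)
  expect_error(genotype_pca(co, k = 20), "k must be smaller")
})

test_that("with no PCs the adjusted scan equals the pooled-variance t-test", {
  set.seed(33)
  n <- 60
  I <- matrix(runif(n * 12, 0.3, 0.9), n, 12)
  phen <- rep(c("CASE", "CONTROL"), c(25, 35))
  prof <- structure(
    list(intensity = I,
         anchors = tibble::tibble(anchor_idx = 1:12,
                                  snp_id = paste0("s", 1:12),
                                  chromosome = "1",
                                  position_bp = 100L * (1:12)),
         W = 5, phenotype = factor(phen, c("CASE", "CONTROL"))),
    class = "intensity_profile"
  )
  adj <- adjusted_scan(prof)
  for (j in c(1, 5, 12)) {
    tt <- t.test(I[phen == "CASE", j], I[phen == "CONTROL", j],
                 var.equal = TRUE)
    expect_equal(adj$estimate[j],
                 unname(diff(rev(tt$estimate))), tolerance = 1e-10)
    expect_equal(10^(-adj$minus_log10_p[j]), tt$p.value, tolerance = 1e-9)
  }
})

test_that("null regressions give uniform p-values and signals are recovered", {
  set.seed(44)
  n <- 400
  phen <- rep(c("CASE", "CONTROL"), each = n / 2)
  null_I <- matrix(runif(n * 500), n, 500)
  prof <- structure(
    list(intensity = null_I,
         anchors = tibble::tibble(anchor_idx = 1:500,
                                  snp_id = paste0("s", 1:500),
                                  chromosome = "1",
                                  position_bp = 100L * (1:500)),
         W = 5, phenotype = factor(phen, c("CASE", "CONTROL"))),
    class = "intensity_profile"
  )
  pvals <- 10^(-adjusted_scan(prof)$minus_log10_p)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)

  # effect recovery: intensity = 0.1 * status + noise
  set.seed(45)
  status <- as.numeric(phen == "CASE")
  sig_I <- matrix(0.1 * status + rnorm(n * 3, 0.5, 0.1), n, 3)
  prof$intensity <- sig_I
  prof$anchors <- prof$anchors[1:3, ]
  adj <- adjusted_scan(prof)
  expect_true(all(abs(adj$estimate - 0.1) < 3 * adj$se))
  expect_true(all(adj$minus_log10_p > 8))
})

test_that("principal components orthogonal to status and intensity barely move p", {
  set.seed(46)
  n <- 500
  phen <- rep(c("CASE", "CONTROL"), each = n / 2)
  I <- matrix(runif(n * 20), n, 20)
  prof <- structure(
    list(intensity = I,
         anchors = tibble::tibble(anchor_idx = 1:20,
                                  snp_id = paste0("s", 1:20),
                                  chromosome = "1",
                                  position_bp = 100L * (1:20)),
         W = 5, phenotype = factor(phen, c("CASE", "CONTROL"))),
    class = "intensity_profile"
  )
  unadj <- adjusted_scan(prof)
  pcs <- matrix(rnorm(n * 5), n, 5)
  status <- as.numeric(phen == "CASE")
  pcs <- stats::resid(lm(pcs ~ status))       # orthogonalise to status
  adj <- adjusted_scan(prof, pcs = pcs)
  expect_lt(max(abs(adj$minus_log10_p - unadj$minus_log10_p)), 0.05)
})

test_that("adjustment attenuates stratification-driven inflation", {
  # subpopulation 2 has more cases and more background homozygosity, so the
  # unadjusted scan inflates; conditioning on PCs attenuates it
  co <- simulate_stratified_cohort(
    n_per_pop = c(300, 300), case_fraction = c(0.3, 0.7), n_snps = 300,
    fst = 0.15, inbreeding_f = c(0, 0.2), seed = 60
  )
  prof <- homozygote_intensity(co, W = 15)
  pca <- genotype_pca(co, k = 5)
  unadj <- adjusted_scan(prof)
  adj <- adjusted_scan(prof, pcs = pca)
  expect_lt(median(adj$minus_log10_p), median(unadj$minus_log10_p))
})

test_that("a collinear design is flagged rather than fitted", {
  n <- 30
  I <- matrix(runif(n * 2), n, 2)
  phen <- rep(c("CASE", "CONTROL"), each = 15)
  prof <- structure(
    list(intensity = I,
         anchors = tibble::tibble(anchor_idx = 1:2, snp_id = c("a", "b"),
                                  chromosome = "1",
                                  position_bp = c(100L, 200L)),
         W = 3, phenotype = factor(phen, c("CASE", "CONTROL"))),
    class = "intensity_profile"
  )
  dup_status <- cbind(as.numeric(phen == "CASE"))
  adj <- adjusted_scan(prof, pcs = dup_status)
  expect_true(attr(adj, "collinear_design"))
  expect_true(all(is.na(adj$minus_log10_p)))
})
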