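test_that("small-sample rank-sum p-values are exact", {
  expect_equal(ranksum_test(c(3, 4, 5), c(0, 1, 2))$p, 1 / 20)
  expect_equal(ranksum_test(c(0, 1), c(2, 3))$p, 1)
  expect_equal(ranksum_test(c(2, 3), c(0, 1))$p, 1 / 6)
  # fully tied data carry no evidence
  expect_equal(ranksum_test(rep(1, 5), rep(1, 7))$p, 1)
  expect_error(ranksum_test(numeric(0), 1:3), "non-missing")
})

test_that("rank-sum implementation agrees with independent references", {
  set.seed(21)
  # tie-free small samples vs R's exact distribution and brute enumeration
  for (i in 1:40) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    got <- ranksum_test(x, y)$p
    want <- stats::wilcox.test(x, y, alternative = "greater",
                               exact = TRUE)$p.value
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(got, enumeration_oracle(x, y), tolerance = 1e-12)
  }
  # tied small samples: enumeration is the reference
  for (i in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(0:2, n1, replace = TRUE); y <- sample(0:2, n2, replace = TRUE)
    expect_equal(ranksum_test(x, y)$p, enumeration_oracle(x, y),
                 tolerance = 1e-12)
  }
  # large samples with ties vs wilcox.test's corrected normal approximation
  for (i in 1:10) {
    x <- sample(seq(0, 1, 0.05), 60, replace = TRUE)
    y <- sample(seq(0, 1, 0.05), 80, replace = TRUE) - 0.05
    got <- ranksum_test(x, y)$p
    want <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "greater", exact = FALSE,
                         correct = TRUE)$p.value
    )
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("the scan reports anchors, medians and carrier proportions", {
  cfg <- cohort_sim_config(n_cases = 40, n_controls = 40, n_snps = 80,
                           L = 20, delta = 1, epsilon = 0)
  sim <- simulate_cohort(cfg, seed = 4)
  scan <- roh_scan(sim, W = 10)
  expect_s3_class(scan, "scan_result")
  expect_equal(nrow(scan), 80)
  expect_true(all(scan$minus_log10_p >= 0))
  expect_true(all(scan$pROH_cases >= 0 & scan$pROH_cases <= 1))
  mid <- (sim$tract_start_idx + sim$tract_end_idx) %/% 2
  # every case carries the tract: pROH_cases = 1 at the tract centre and the
  # tract is the top signal
  expect_equal(scan$pROH_cases[mid], 1)
  expect_lt(scan$pROH_controls[mid], 0.5)
  expect_gt(scan$minus_log10_p[mid], max(scan$minus_log10_p[c(1:5, 76:80)]))
})

test_that("carrier calls follow the threshold contract", {
  g <- matrix(c(rep(0L, 12), rep(1L, 4)), 4, 4) # 3 hom columns, 1 het column
  co <- toy_cohort(g, c("CASE", "CASE", "CONTROL", "CONTROL"))
  prof <- homozygote_intensity(co, W = 3)
  cc <- call_carriers(prof, threshold = 0.95)
  expect_equal(cc$proh$pROH_cases[1], 1)
  # intensities all far below 0.5: no carriers at threshold 0.5
  low <- call_carriers(
    structure(list(intensity = matrix(0.4, 4, 2),
                   anchors = tibble::tibble(snp_id = c("a", "b")),
                   phenotype = co$phenotype),
              class = "intensity_profile"),
    threshold = 0.5
  )
  expect_equal(low$proh$pROH_cases, c(0, 0))
  expect_error(call_carriers(prof, threshold = 1.2), "threshold")
})

test_that("significant regions merge maximal runs of consecutive anchors", {
  scan <- tibble::tibble(
    chromosome = "1", position_bp = c(100L, 200L, 300L, 400L),
    snp_id = paste0("s", 1:4),
    minus_log10_p = c(9, 9, 3, 10)
  )
  reg <- significant_regions(scan, 8)
  expect_equal(nrow(reg), 2)
  expect_equal(reg$start_bp, c(100L, 400L))
  expect_equal(reg$end_bp, c(200L, 400L))
  expect_equal(reg$peak_minus_log10_p, c(9, 10))
  expect_equal(nrow(significant_regions(scan, 20)), 0)
  # runs do not merge across chromosomes
  scan2 <- scan; scan2$chromosome <- c("1", "2", "2", "2")
  scan2$minus_log10_p <- c(9, 9, 9, 9)
  expect_equal(nrow(significant_regions(scan2, 8)), 2)
})

test_that("permuting individuals permutes KL rows with no hidden state", {
  set.seed(8)
  g <- matrix(sample(c(0L, 1L, 2L), 300, replace = TRUE), 15, 20)
  co <- toy_cohort(g, rep(c("CASE", "CONTROL"), c(7, 8)))
  klp <- kl_profile(homozygote_intensity(co, W = 5))
  perm <- sample(15)
  co2 <- roh_cohort(g[perm, ], co$map, as.character(co$phenotype)[perm])
  rownames(co2$genotypes) <- rownames(g)[perm]
  klp2 <- kl_profile(homozygote_intensity(co2, W = 5))
  expect_equal(unname(klp2$kl), unname(klp$kl[perm, ]), tolerance = 1e-12)
  # and the scan p-values are unchanged by the relabelling-consistent permute
  s1 <- wilcoxon_scan(klp)
  s2 <- wilcoxon_scan(klp2)
  expect_equal(s2$minus_log10_p, s1$minus_log10_p, tolerance = 1e-9)
})

test_that("glance summarises a scan", {
  cfg <- cohort_sim_config(n_cases = 20, n_controls = 20, n_snps = 40,
                           L = 10, delta = 1)
  sc <- roh_scan(simulate_cohort(cfg, seed = 2), W = 5)
  gl <- glance(sc)
  expect_equal(gl$n_anchors, 40L)
  expect_equal(gl$W, 5)
})
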