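test_that("well-separated classes approach the Bayes rate and null features sit at chance", {
  set.seed(2)
  phen <- rep(c("CASE", "CONTROL"), each = 2000)
  x <- c(rnorm(2000, 4), rnorm(2000, 0))
  cv <- lda_cv_accuracy(x, phen, seed = 1)
  expect_gte(cv$mean_accuracy, 0.97) # Bayes rate for a 4-sigma shift is 0.977

  phen <- rep(c("CASE", "CONTROL"), each = 500)
  acc <- vapply(1:20, function(s) {
    set.seed(100 + s)
    lda_cv_accuracy(rnorm(1000), phen, seed = s)$mean_accuracy
  }, numeric(1))
  expect_gt(mean(acc), 0.45)
  expect_lt(mean(acc), 0.55)
})

test_that("a feature equal to the label is perfectly predictive", {
  phen <- rep(c("CASE", "CONTROL"), each = 30)
  x <- as.numeric(phen == "CASE") + rnorm(60, sd = 0.01)
  cv <- lda_cv_accuracy(x, phen, seed = 3)
  expect_equal(cv$mean_accuracy, 1)
  expect_equal(cv$mean_accuracy,
               sum(cv$folds$accuracy * cv$folds$n) / sum(cv$folds$n))
})

test_that("zero-variance training folds fall back to the majority class", {
  phen <- rep(c("CASE", "CONTROL"), c(20, 30))
  x <- rep(1, 50) # constant feature: every fold is degenerate
  cv <- lda_cv_accuracy(x, phen, k_folds = 5, seed = 1)
  expect_equal(cv$mean_accuracy, 0.6) # majority = CONTROL = 30/50
})

test_that("accuracy is invariant to monotone rescaling of one feature", {
  set.seed(9)
  phen <- rep(c("CASE", "CONTROL"), each = 100)
  x <- c(rnorm(100, 1), rnorm(100, 0))
  a <- lda_cv_accuracy(x, phen, seed = 7)$mean_accuracy
  b <- lda_cv_accuracy(10 * x - 3, phen, seed = 7)$mean_accuracy
  expect_equal(a, b)
})

test_that("best_anchor takes the argmax with positional tie-breaking", {
  res <- tibble::tibble(snp_id = c("a", "b", "c"),
                        position_bp = c(100L, 200L, 300L),
                        mean_accuracy = c(0.55, 0.62, 0.58))
  expect_equal(best_anchor(res)$snp_id, "b")
  res$mean_accuracy <- rep(0.5, 3)
  expect_equal(best_anchor(res)$snp_id, "a")
})

test_that("the most accurate anchor lies inside the embedded tract", {
  hits <- vapply(1:10, function(s) {
    cfg <- cohort_sim_config(n_cases = 120, n_controls = 180, n_snps = 120,
                             L = 40, delta = 0.4)
    sim <- simulate_cohort(cfg, seed = 700 + s)
    prof <- homozygote_intensity(sim, W = 20)
    cv <- predict_status_cv(prof, anchors = prof$anchors$snp_id[seq(5, 115, 10)],
                            seed = s)
    best <- best_anchor(cv)
    idx <- match(best$snp_id, sim$map$snp_id)
    idx >= sim$tract_start_idx - 20 && idx <= sim$tract_end_idx + 20
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("category tables partition each group", {
  phen <- rep(c("CASE", "CONTROL"), c(40, 60))
  # no carriers anywhere
  none <- matrix(FALSE, 100, 3,
                 dimnames = list(NULL, c("t1", "t2", "t3")))
  tab <- category_table(none, phen)
  expect_equal(nrow(tab), 8)
  expect_equal(tab$pROH_cases[tab$category == "(0,0,0)"], 1)
  expect_equal(tab$pROH_controls[tab$category == "(0,0,0)"], 1)
  expect_equal(sum(tab$pROH_cases), 1)
  expect_equal(sum(tab$pROH_controls), 1)

  set.seed(11)
  carriers <- matrix(runif(300) < 0.3, 100, 3)
  tab2 <- category_table(carriers, phen, min_proportion = 0.02)
  expect_equal(sum(tab2$pROH_cases), 1)
  expect_equal(sum(tab2$pROH_controls), 1)
  expect_equal(tab2$risk, tab2$pROH_cases > tab2$pROH_controls)
  expect_equal(tab2$reported, tab2$pROH_cases > 0.02)
})

test_that("the delta fraction of cases shows up as the single-anchor carrier category", {
  cfg <- cohort_sim_config(n_cases = 400, n_controls = 400, n_snps = 80,
                           L = 30, delta = 0.3)
  sim <- simulate_cohort(cfg, seed = 15)
  prof <- homozygote_intensity(sim, W = 10)
  mid <- (sim$tract_start_idx + sim$tract_end_idx) %/% 2
  cc <- call_carriers(prof)
  tab <- category_table(cc$carriers[, mid, drop = FALSE], sim$phenotype)
  p1 <- tab$pROH_cases[tab$category == "(1)"]
  expect_lt(abs(p1 - 0.3), 0.05)
})

test_that("tag anchors summarise blocks of matching carrier patterns", {
  phen <- rep(c("CASE", "CONTROL"), each = 50)
  base <- matrix(FALSE, 100, 5)
  base[1:20, ] <- TRUE # identical carrier sets at all five anchors
  tags <- select_tag_anchors(base, phen, positions = 100L * (1:5))
  expect_equal(length(unique(tags$group)), 1)
  expect_equal(sum(tags$tag), 1)

  two <- cbind(base[, 1:2], matrix(FALSE, 100, 2))
  two[31:45, 3:4] <- TRUE # disjoint carrier block
  tags2 <- select_tag_anchors(two, phen, positions = 100L * (1:4))
  expect_equal(length(unique(tags2$group)), 2)
  expect_equal(sum(tags2$tag), 2)
})

test_that("two embedded tracts yield one tag anchor inside each", {
  ok <- vapply(1:10, function(s) {
    set.seed(800 + s)
    n <- 200; m <- 90
    maf <- runif(m, 0.05, 0.5)
    g <- rohscan:::cpp_sim_genotypes(n, maf)
    phen <- rep(c("CASE", "CONTROL"), each = 100)
    carA <- sample(1:100, 40)
    carB <- sample(setdiff(1:100, carA), 40)
    for (i in carA) g[i, 11:35] <- ifelse(runif(25) < maf[11:35], 2L, 0L)
    for (i in carB) g[i, 56:80] <- ifelse(runif(25) < maf[56:80], 2L, 0L)
    co <- toy_cohort(g, phen)
    prof <- homozygote_intensity(co, W = 15)
    cc <- call_carriers(prof)
    # tag selection operates on the strongly carrying anchors, as it would
    # on the anchors inside significant regions (delta = 0.4 here, so the
    # carrying anchors sit near pROH 0.4; truncated map-edge windows are
    # noisier and fall below the cut)
    anchors <- which(cc$proh$pROH_cases > 0.3)
    tags <- select_tag_anchors(cc$carriers[, anchors, drop = FALSE],
                               co$phenotype,
                               positions = co$map$position_bp[anchors],
                               jaccard_threshold = 0.5)
    picked <- anchors[tags$anchor[tags$tag]]
    sum(tags$tag) == 2 &&
      any(picked >= 11 & picked <= 35) && any(picked >= 56 & picked <= 80)
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})
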