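test_that("rank-sum U and exact p match closed forms and enumeration", {
  res <- rankSumTest(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3)  # 2 / C(4,2)
  expect_equal(res$method, "exact")

  same <- rankSumTest(c(5, 9, 13), c(5, 9, 13))
  expect_equal(same$p_value, 1)

  set.seed(101)
  for (rep in 1:15) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- sample(seq_len(100), n1); y <- sample(setdiff(seq_len(200), x), n2)
    alt <- sample(c("two.sided", "less", "greater"), 1)
    res <- rankSumTest(x, y, alt)
    expect_equal(res$p_value, enumRankSumP(x, y, alt), tolerance = 1e-12)
    expect_true(res$statistic >= 0 && res$statistic <= n1 * n2)
  }

  big <- rankSumTest(rnorm(150), rnorm(150))
  expect_equal(big$method, "normal_approx")
  expect_error(rankSumTest(numeric(0), 1:3), "non-empty")
})

test_that("repression test detects a planted shift and reports medians", {
  set.seed(102)
  sim <- simulateExpressionMatrix(nGenes = 200, nTargets = 100,
                                  repressionDelta = -2, seed = 102)
  res <- compareDomainGeneExpression(sim$expr, sim$targetGenes,
                                     samples = sim$tumorSamples)
  expect_lt(res$p_value, 1e-6)
  expect_lt(res$median_domain, res$median_background)

  # extreme separation gives the minimal one-sided p for the group sizes
  m <- rbind(matrix(0, 5, 4), matrix(5, 45, 4))
  rownames(m) <- paste0("g", 1:50); colnames(m) <- paste0("s", 1:4)
  ext <- compareDomainGeneExpression(m, paste0("g", 1:5))
  expect_equal(ext$p_value, 1 / choose(50, 5), tolerance = 1e-6)

  expect_error(compareDomainGeneExpression(m, c("g1", "g2")), ">= 3")
})

test_that("null repression p-values are roughly uniform", {
  ps <- vapply(1:60, function(i) {
    sim <- simulateExpressionMatrix(nGenes = 60, nTargets = 20,
                                    nTumor = 10, nNormal = 5,
                                    repressionDelta = 0, seed = 4000 + i)
    compareDomainGeneExpression(sim$expr, sim$targetGenes,
                                samples = sim$tumorSamples)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("correlation report covers both coefficients and the fit line", {
  x <- c(1, 2, 3, 4, 5)
  res <- correlationTest(x, -x)
  expect_equal(res$pearson_r, -1)
  expect_equal(res$spearman_rho, -1)
  expect_equal(res$slope, -1)
  expect_equal(res$intercept, 0)

  mono <- correlationTest(x, exp(-x))
  expect_equal(mono$spearman_rho, -1)
  expect_gt(mono$pearson_r, -1)

  expect_error(correlationTest(x, rep(2, 5)), "y")
  expect_error(correlationTest(rep(1, 5), x), "x")
  expect_error(correlationTest(1:2, 2:3), "n >= 3")
})

test_that("AUC equals pair enumeration and the Youden cutoff behaves", {
  perfect <- rocAnalysis(c(5, 6, 7, 1, 2, 3),
                         c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity_at_cutoff, 1)
  expect_equal(perfect$specificity_at_cutoff, 1)

  res <- rocAnalysis(c(4, 2, 3, 1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$auc, 0.75)  # 3 of 4 concordant pairs

  set.seed(103)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    scores <- round(rnorm(n), sample(c(0, 1, 3), 1))  # induce some ties
    labels <- sample(c(TRUE, FALSE), n, TRUE)
    if (!any(labels) || all(labels)) next
    r <- rocAnalysis(scores, labels)
    expect_equal(r$auc, bruteAuc(scores, labels))
    # invariant under strictly monotone transform of the scores
    r2 <- rocAnalysis(exp(scores / 2), labels)
    expect_equal(r2$auc, r$auc)
    expect_equal(r2$sensitivity_at_cutoff, r$sensitivity_at_cutoff)
    expect_equal(r2$specificity_at_cutoff, r$specificity_at_cutoff)
    # curve sanity: starts (0,0), ends (1,1), monotone
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[nrow(r$points)], 1)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
  }
  expect_error(rocAnalysis(1:4, c(TRUE, TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(104)
  scores <- rnorm(80)
  labels <- sample(c(TRUE, FALSE), 80, TRUE)
  ours <- rocAnalysis(scores, labels)
  ref <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                   direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  yj <- pROC::coords(ref, "best", best.method = "youden",
                     ret = c("sensitivity", "specificity"))
  expect_equal(ours$sensitivity_at_cutoff + ours$specificity_at_cutoff,
               max(yj$sensitivity + yj$specificity), tolerance = 1e-9)
})

test_that("over-representation reproduces hypergeometric closed forms", {
  universe <- paste0("g", 1:10)
  sets <- list(hitset = paste0("g", 1:5),
               offset = paste0("g", 6:10))
  res <- overRepresentation(paste0("g", 1:5), sets, universe)
  expect_equal(res$p_value[res$set == "hitset"], 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(res$p_value[res$set == "offset"], 1)  # k = 0 upper tail
  expect_true(all(res$adj_p_value >= res$p_value))

  # BH step-up on (0.01, 0.02, 0.03) -> all 0.03; check via p.adjust contract
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))

  expect_error(overRepresentation("gX", sets, universe), "not in universe")
  expect_error(overRepresentation(character(), sets, universe), "empty hit")
})

test_that("driver split is deterministic with lexicographic tie-breaks", {
  m <- matrix(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1), 1,
              dimnames = list("EZH2", paste0("s", sprintf("%02d", 1:10))))
  sp <- splitByDriver(m, "EZH2", nPerGroup = 3)
  expect_equal(sp$high, c("s01", "s02", "s03"))
  expect_equal(sp$low, c("s10", "s09", "s08"))
  expect_length(intersect(sp$high, sp$low), 0)

  tied <- matrix(rep(1, 6), 1,
                 dimnames = list("EZH2", c("b", "a", "d", "c", "f", "e")))
  sp2 <- splitByDriver(tied, "EZH2", nPerGroup = 2)
  expect_equal(sp2$high, c("a", "b"))
  expect_equal(sp2$low, c("a", "b"))  # identical values: rank = id order
  expect_error(splitByDriver(m, "EZH2", nPerGroup = 6), "need >= 12")
  expect_error(splitByDriver(m, "nope"), "absent")
})

test_that("signature scores are mean gene z-scores with contract errors", {
  m <- matrix(c(2, 4, 6), 1, dimnames = list("g1", paste0("s", 1:3)))
  sc <- signatureScore(m, "g1")
  expect_equal(unname(sc), c(-1, 0, 1))  # sample sd = 2

  scPop <- signatureScore(m, "g1", sdMethod = "population")
  expect_equal(unname(scPop), c(-1, 0, 1) * sqrt(3 / 2))

  flat <- rbind(m, g2 = c(5, 5, 5))
  expect_error(signatureScore(flat, c("g1", "g2")), "zero-variance")
  expect_warning(s <- signatureScore(m, c("g1", "gMissing")), "absent")
  expect_error(signatureScore(m, "gMissing"), "entirely absent")
})

test_that("a planted repressed-in-high signature separates driver cohorts", {
  set.seed(105)
  nS <- 60
  samples <- sprintf("s%02d", seq_len(nS))
  driver <- rnorm(nS)
  sig <- t(vapply(1:25, function(i) -driver + rnorm(nS), numeric(nS)))
  other <- matrix(rnorm(75 * nS), 75)
  m <- rbind(matrix(driver, 1), sig, other)
  rownames(m) <- c("DRV", paste0("sig", 1:25), paste0("x", 1:75))
  colnames(m) <- samples
  sp <- splitByDriver(m, "DRV", nPerGroup = 20)
  sc <- signatureScore(m, paste0("sig", 1:25))
  res <- rankSumTest(sc[sp$high], sc[sp$low], alternative = "less")
  expect_lt(res$p_value, 0.01)
})
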