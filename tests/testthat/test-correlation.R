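test_that("Spearman: monotone relations, ties, and the t-approximation p-value", {
  x <- c(1, 3, 7, 9, 12)
  expect_equal(spearmanRho(x, 2 * x + 1)$rho, 1)
  expect_equal(spearmanRho(x, -x^3)$rho, -1)
  expect_equal(spearmanRho(x, x)$p, .Machine$double.xmin)

  # tied data match the independent implementation in stats::cor
  set.seed(10)
  for (rep in 1:100) {
    n <- sample(4:40, 1)
    x <- round(runif(n, 0, 6))
    y <- round(rnorm(n, x, 2))
    if (var(x) == 0 || var(y) == 0) next
    expect_equal(spearmanRho(x, y)$rho,
                 cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
  expect_equal(spearmanRho(c(1, 2, 2, 3), c(10, 20, 20, 40))$rho,
               cor(c(1, 2, 2, 3), c(10, 20, 20, 40), method = "spearman"),
               tolerance = 1e-12)

  # p-value equals the two-sided t approximation
  set.seed(2)
  x <- rnorm(20); y <- x + rnorm(20, 0, 2)
  s <- spearmanRho(x, y)
  tt <- s$rho * sqrt(18 / (1 - s$rho^2))
  expect_equal(s$p, 2 * pt(-abs(tt), 18))

  # zero rank variance -> undefined
  expect_true(is.na(spearmanRho(rep(1, 5), 1:5)$rho))
  expect_error(spearmanRho(1:2, 1:2), "at least 3")
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(5)
  trans <- list(function(v) exp(v), function(v) v^3,
                function(v) -1 / (1 + exp(-v)), function(v) 5 * v - 2)
  for (rep in 1:20) {
    x <- rnorm(25)
    y <- rnorm(25, x)
    base <- spearmanRho(x, y)$rho
    f <- trans[[1 + rep %% 4]]
    decreasing <- f(1) < f(0)
    expect_equal(spearmanRho(f(x), y)$rho, if (decreasing) -base else base,
                 tolerance = 1e-12)
  }
})

test_that("significance stars follow the reporting thresholds", {
  expect_identical(significanceStars(0.04), "*")
  expect_identical(significanceStars(0.004), "***")
  expect_identical(significanceStars(0.5), "")
  expect_identical(significanceStars(0.007), "**")
})

test_that("spec enumeration counts match the combinatorial product", {
  c1 <- runConfig(scenarios = "FULL_LR_TOGETHER", nGrid = c(10, 50, 90),
                  valueKinds = "raw")
  expect_identical(nrow(enumerateSpecs(c1)), 9L) # 6 non-P_N + 3 P_N

  c2 <- runConfig(scenarios = "VORONOI_LR_SPLIT", radii = c(10, 20),
                  nGrid = c(10, 50, 90), valueKinds = "raw")
  expect_identical(nrow(enumerateSpecs(c2)), 2L * 9L * 9L * 9L)

  cfg <- runConfig("coarse")
  nInter <- length(cfg$nGrid) + 6L
  nR <- length(cfg$radii)
  expected <- 2L * (nInter + nInter * 9L + nR * 9L * nInter +
                      nR * 9L * nInter * 9L)
  expect_identical(nrow(enumerateSpecs(cfg)), expected)
  expect_identical(anyDuplicated(enumerateSpecs(cfg)$id), 0L)
})

test_that("rankSpecs: dominance, truncation, pairwise deletion and sort oracle", {
  set.seed(33)
  n <- 12
  truthScore <- sort(rnorm(n))
  scores <- cbind(
    engineered = truthScore,
    noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n),
    undef = c(NA, rnorm(n - 1)))
  rownames(scores) <- sprintf("c%02d", 1:n)
  pft <- data.frame(case_id = rownames(scores),
                    dlco_pct = c(rep(NA, 3), rnorm(n - 3, 70, 10)),
                    fev1_pct = 100 - rank(truthScore), # strictly monotone
                    fvc_pct = rnorm(n, 90, 5),
                    fev1_fvc = rnorm(n, 75, 5))
  top <- rankSpecs(scores, pft, "FEV1", k = 2)
  expect_identical(top$id[1], "engineered")
  expect_equal(abs(top$rho[1]), 1)
  expect_identical(top$n[1], as.integer(n))

  # undefined-for-one-case specs are dropped entirely
  all4 <- rankSpecs(scores, pft, "FEV1", k = 100)
  expect_identical(nrow(all4), 4L)
  expect_false("undef" %in% all4$id)

  # DLCO uses exactly the cases with DLCO present
  expect_identical(rankSpecs(scores, pft, "DLCO", k = 1)$n,
                   as.integer(n) - 3L)

  # ranking equals an independent sort over per-spec spearmanRho calls
  oracle <- vapply(colnames(scores)[1:4], function(id) {
    spearmanRho(scores[, id], pft$fev1_pct)$rho
  }, numeric(1))
  ord <- names(sort(-abs(oracle)))
  expect_identical(all4$id, ord)
  expect_equal(all4$rho, unname(oracle[ord]), tolerance = 1e-12)
})

test_that("searchCorrelations skips unusable measures and reports per-scenario bests", {
  set.seed(1)
  mask <- boxMask()
  cohort <- lapply(1:6, function(i)
    list(caseId = sprintf("c%d", i), grid = randomGrid(mask, i), mask = mask))
  cfg <- runConfig("coarse", radii = 10, nGrid = c(20, 80),
                   nRealizations = 1, baseSeed = 2, valueKinds = "raw")
  M <- scoreCohort(cohort, cfg)
  pft <- data.frame(case_id = sprintf("c%d", 1:6),
                    dlco_pct = NA_real_, # too few cases -> skipped
                    fev1_pct = runif(6, 50, 100),
                    fvc_pct = runif(6, 50, 100),
                    fev1_fvc = runif(6, 50, 100))
  expect_warning(res <- searchCorrelations(M, pft, topK = 3), "DLCO")
  expect_false("DLCO" %in% names(res$topk))
  expect_identical(nrow(res$topk$FEV1), 3L)
  expect_identical(res$topk$FEV1$id[1],
                   rankSpecs(M, pft, "FEV1", k = 1)$id)
  expect_true(all(res$heatmap$scenario == c("FULL_LR_TOGETHER",
                                            "FULL_LR_SPLIT",
                                            "VORONOI_LR_TOGETHER",
                                            "VORONOI_LR_SPLIT")))
  expect_true(all(abs(res$heatmap$FEV1) <= 1, na.rm = TRUE))
})
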