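test_that("degenerate one-subvolume partitions reduce to whole-lung statistics", {
  mask <- boxMask()
  grid <- randomGrid(mask, seed = 5)
  parts <- partitionRealizations(mask, radius = 60, nRealizations = 1,
                                 baseSeed = 3)
  expect_length(subvolumeSizes(parts[[1]]$left), 1L)

  vl <- voxelValues(grid)[maskLabels(mask) == 1L]
  vr <- voxelValues(grid)[maskLabels(mask) == 2L]

  # VORONOI L+R with intra = inter = MEDIAN: median of the two lung medians
  spTog <- metricSpec("VORONOI_LR_TOGETHER", radius = 60,
                      intraMetric = "MEDIAN", interMetric = "MEDIAN")
  expect_equal(globalScore(grid, mask, spTog, parts),
               median(c(median(vl), median(vr))))

  # FULL L/R with inter = MEDIAN, lr = AVG: mean of the two medians
  spFull <- metricSpec("FULL_LR_SPLIT", interMetric = "MEDIAN",
                       lrMetric = "AVG")
  expect_equal(globalScore(grid, mask, spFull),
               mean(c(median(vl), median(vr))))

  # FULL L+R applies the inter statistic to the pooled voxels directly
  spPool <- metricSpec("FULL_LR_TOGETHER", interMetric = "P75")
  pooled <- voxelValues(grid)[maskLabels(mask) > 0L]
  expect_equal(globalScore(grid, mask, spPool),
               unname(quantile(pooled, 0.75, type = 7)))
})

test_that("with one subvolume per lung the Voronoi split path equals the Full split path", {
  mask <- boxMask()
  grid <- randomGrid(mask, seed = 9)
  parts <- partitionRealizations(mask, radius = 60, nRealizations = 2,
                                 baseSeed = 8)
  for (m in c("MEDIAN", "P25", "P75")) {
    for (lr in c("AVG", "MIN", "VOL_WEIGHTED_AVG")) {
      spV <- metricSpec("VORONOI_LR_SPLIT", radius = 60, intraMetric = m,
                        interMetric = m, lrMetric = lr)
      spF <- metricSpec("FULL_LR_SPLIT", interMetric = m, lrMetric = lr)
      expect_identical(globalScore(grid, mask, spV, parts),
                       globalScore(grid, mask, spF))
    }
  }
})

test_that("Voronoi scores are deterministic and average over realizations", {
  mask <- boxMask()
  grid <- randomGrid(mask, seed = 2)
  sp <- metricSpec("VORONOI_LR_SPLIT", radius = 4, intraMetric = "P75",
                   interMetric = "P_N", nThreshold = 80, lrMetric = "AVG")
  parts <- partitionRealizations(mask, 4, 5, baseSeed = 77)
  s1 <- globalScore(grid, mask, sp, parts)
  s2 <- globalScore(grid, mask, sp,
                    partitionRealizations(mask, 4, 5, baseSeed = 77))
  expect_identical(s1, s2)
  singles <- vapply(parts, function(p) globalScore(grid, mask, sp, list(p)),
                    numeric(1))
  expect_equal(s1, mean(singles))
  expect_error(globalScore(grid, mask, sp, NULL), "partitions")
})

test_that("the score-matrix sweep is bit-identical to spec-by-spec evaluation", {
  cfg <- runConfig("coarse", radii = c(4, 8), nGrid = c(20, 60, 90),
                   nRealizations = 2, baseSeed = 19)
  mask <- boxMask()
  cohort <- list(list(caseId = "a", grid = randomGrid(mask, 1), mask = mask),
                 list(caseId = "b", grid = randomGrid(mask, 2), mask = mask))
  M <- scoreCohort(cohort, cfg)
  specs <- attr(M, "specs")
  expect_identical(nrow(specs), ncol(M))
  set.seed(4)
  for (i in sample(nrow(specs), 25)) {
    row <- specs[i, ]
    sp <- metricSpec(row$scenario, row$radius, row$intraMetric,
                     row$interMetric, row$nThreshold, row$lrMetric,
                     row$valueKind)
    for (ci in 1:2) {
      parts <- NULL
      if (grepl("VORONOI", row$scenario)) {
        j <- match(row$radius, cfg$radii)
        parts <- partitionRealizations(
          mask, row$radius, cfg$nRealizations,
          partitionSeed(cfg$baseSeed, ci, j), cfg$kAttempts)
      }
      expect_identical(
        unname(M[ci, row$id]),
        globalScore(cohort[[ci]]$grid, cohort[[ci]]$mask, sp, parts))
    }
  }
})

test_that("spec ids round-trip through parseSpecId", {
  cfg <- runConfig("coarse", radii = c(10, 25.5), nGrid = c(5, 89.6))
  specs <- enumerateSpecs(cfg)
  set.seed(6)
  for (i in sample(nrow(specs), 30)) {
    sp <- parseSpecId(specs$id[i])
    expect_identical(specId(sp), specs$id[i])
  }
  expect_error(metricSpec("FULL_LR_TOGETHER", radius = 10,
                          interMetric = "MEDIAN"), "radius")
  expect_error(metricSpec("VORONOI_LR_SPLIT", radius = 10,
                          intraMetric = "MEDIAN", interMetric = "P_N",
                          nThreshold = 99, lrMetric = "AVG"), "N threshold")
})
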