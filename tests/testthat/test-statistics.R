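test_that("intra statistics reproduce closed-form values on simple inputs", {
  v <- c(1, 2, 3, 4, 5)
  expect_equal(intraStat(v, "MEDIAN"), 3)
  expect_equal(intraStat(v, "P25"), 2)
  expect_equal(intraStat(v, "P75"), 4)
  expect_equal(intraStat(v, "MEAN"), 3)
  expect_equal(intraStat(v, "MIN"), 1)
  expect_equal(intraStat(v, "MAX"), 5)

  # constant multiset: zero variance
  k <- rep(2.5, 17)
  expect_equal(intraStat(k, "SKEWNESS"), 0)
  expect_equal(intraStat(k, "COV"), 0)
  expect_equal(intraStat(k, "MODE_OVER_MEDIAN"), 1)

  # undefined markers are values, not errors
  z <- c(-1, 0, 1)
  expect_true(is.na(intraStat(z, "COV")))
  expect_true(is.na(intraStat(z, "MODE_OVER_MEDIAN")))
  expect_error(intraStat(numeric(0), "MEAN"), "empty")
})

test_that("skewness of a right-skewed mixture matches the moment formula", {
  set.seed(7)
  x <- c(rnorm(800, 0, 1), rnorm(200, 6, 2)) # stated right-skewed mixture
  expect_equal(intraStat(x, "SKEWNESS"), oracleStats(x, "SKEWNESS"),
               tolerance = 1e-12)
  expect_gt(intraStat(x, "SKEWNESS"), 0)
})

test_that("every intra/inter statistic matches an independent oracle on random multisets", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(1:1000, 1)
    x <- switch(1 + rep %% 4,
                rnorm(n, 5, 2),
                rexp(n),
                round(runif(n, 0, 10)), # heavy ties
                rep(runif(1), n)) # constant
    for (m in c("MIN", "MAX", "MEDIAN", "MEAN", "COV", "P25", "P75",
                "SKEWNESS", "MODE_OVER_MEDIAN")) {
      got <- intraStat(x, m)
      want <- oracleStats(x, m)
      if (is.na(want)) expect_true(is.na(got)) else
        expect_equal(got, want, tolerance = 1e-10)
    }
    w <- sample(1:50, length(x), replace = TRUE)
    for (m in c("COV", "MODE_OVER_MEDIAN", "MEDIAN", "P25", "P75",
                "SKEWNESS")) {
      got <- interStat(x, w, m)
      want <- oracleStats(x, m)
      if (is.na(want)) expect_true(is.na(got)) else
        expect_equal(got, want, tolerance = 1e-10)
    }
    N <- runif(1, 5, 95)
    expect_equal(interStat(x, w, "P_N", N), oraclePn(x, w, N),
                 tolerance = 1e-10)
  }
})

test_that("P_N: worked examples and monotonicity in N", {
  expect_equal(interStat(c(10, 5, 1), c(1, 1, 1), "P_N", 95), 200 / 3)
  # constant positive subvalues, N < 100: cutoff is strictly below the value
  expect_equal(interStat(rep(4, 6), rep(2, 6), "P_N", 80), 0)
  # weighted case: only the low subvalue (weight 9) is at or below 50% of max
  expect_equal(interStat(c(1, 10), c(9, 1), "P_N", 50), 90)

  set.seed(1)
  for (rep in 1:100) {
    v <- rexp(sample(2:40, 1)) + 0.01
    w <- sample(1:9, length(v), replace = TRUE)
    grid <- sort(runif(12, 5, 95))
    pn <- vapply(grid, function(N) interStat(v, w, "P_N", N), numeric(1))
    expect_true(all(diff(pn) >= 0))
  }
  # cutoff below the minimum (positive data) -> 0
  expect_equal(interStat(c(50, 60, 100), c(1, 1, 1), "P_N", 20), 0)
})

test_that("COV and skewness are invariant under positive rescaling", {
  set.seed(3)
  for (rep in 1:20) {
    x <- rexp(200) + 0.1
    s <- runif(1, 0.01, 100)
    expect_equal(intraStat(s * x, "COV"), intraStat(x, "COV"),
                 tolerance = 1e-12)
    expect_equal(intraStat(s * x, "SKEWNESS"), intraStat(x, "SKEWNESS"),
                 tolerance = 1e-12)
  }
})

test_that("left-right operators: symmetry, weighting and selectors", {
  for (op in c("MIN", "MAX", "AVG", "VOL_WEIGHTED_AVG", "PERF_WEIGHTED_AVG",
               "LARGEST_VOL", "SMALLEST_VOL", "MOST_PERF", "LEAST_PERF"))
    expect_equal(lrCombine(3.3, 3.3, 100, 200, 10, 20, op), 3.3)

  expect_equal(lrCombine(2, 6, 300, 100, 1, 1, "VOL_WEIGHTED_AVG"), 3)
  expect_equal(lrCombine(2, 6, 300, 100, 1, 1, "LARGEST_VOL"), 2)
  expect_equal(lrCombine(2, 6, 100, 300, 1, 1, "LARGEST_VOL"), 6)
  expect_equal(lrCombine(2, 6, 100, 300, 1, 1, "SMALLEST_VOL"), 2)
  expect_equal(lrCombine(2, 6, 1, 1, 9, 1, "MOST_PERF"), 2)
  expect_equal(lrCombine(2, 6, 1, 1, 1, 9, "LEAST_PERF"), 2)
  expect_equal(lrCombine(2, 6, 1, 1, 3, 1, "PERF_WEIGHTED_AVG"), 3)
  # ties select the left lung
  expect_equal(lrCombine(2, 6, 100, 100, 5, 5, "LARGEST_VOL"), 2)
  expect_equal(lrCombine(2, 6, 100, 100, 5, 5, "MOST_PERF"), 2)
  # undefined marker
  expect_true(is.na(lrCombine(2, 6, 1, 1, 0, 0, "PERF_WEIGHTED_AVG")))
  expect_true(is.na(lrCombine(NA_real_, 6, 1, 1, 1, 1, "AVG")))
})

test_that("percentile map: average ranks per lung, (0,1], invariances", {
  lab <- array(0L, c(4L, 2L, 2L))
  lab[, 1, 1] <- 1L
  lab[, 2, 2] <- 2L
  mask <- LungMask(lab, 2)
  vals <- array(0, dim(lab))
  vals[, 1, 1] <- c(3, 1, 4, 2)
  vals[, 2, 2] <- c(30, 10, 40, 20) # same order structure in the right lung
  pm <- toPercentileMap(VolumeGrid(vals, 2), mask)
  expect_equal(voxelValues(pm)[, 1, 1], c(0.75, 0.25, 1, 0.5))
  # identical value ranks -> identical percentile multisets across lungs
  expect_equal(voxelValues(pm)[, 2, 2], c(0.75, 0.25, 1, 0.5))

  # constant lung -> (n+1)/(2n) everywhere
  vals[, 1, 1] <- 5
  pc <- toPercentileMap(VolumeGrid(vals, 2), mask)
  expect_equal(voxelValues(pc)[, 1, 1], rep(5 / 8, 4))

  # invariance under strictly increasing transforms; range (0,1]
  mask2 <- boxMask()
  g <- randomGrid(mask2, seed = 8)
  p1 <- toPercentileMap(g, mask2)
  g2 <- VolumeGrid(exp(2 * voxelValues(g)) + 1, voxelSpacing(g))
  p2 <- toPercentileMap(g2, mask2)
  sel <- maskLabels(mask2) > 0
  expect_identical(voxelValues(p1)[sel], voxelValues(p2)[sel])
  expect_true(all(voxelValues(p1)[sel] > 0 & voxelValues(p1)[sel] <= 1))
})
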