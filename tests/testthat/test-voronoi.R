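test_that("Bridson sampling honours the spacing contract and determinism", {
  mask <- boxMask()
  s1 <- sampleSeedsBridson(mask, 1L, radius = 3, rngSeed = 11)
  s2 <- sampleSeedsBridson(mask, 1L, radius = 3, rngSeed = 11)
  expect_identical(seedPoints(s1), seedPoints(s2))

  pts <- seedPoints(s1)
  expect_gt(nrow(pts), 1)
  dd <- as.matrix(dist(pts))
  expect_true(all(dd[upper.tri(dd)] >= 3))

  # every seed's containing voxel carries the lung label
  vox <- round(pts) + 1L
  expect_true(all(maskLabels(mask)[vox] == 1L))

  # radius beyond the lung diameter -> a single seed
  sBig <- sampleSeedsBridson(mask, 1L, radius = 60, rngSeed = 5)
  expect_identical(nrow(seedPoints(sBig)), 1L)

  # different seeds differ (non-degenerate lung)
  s3 <- sampleSeedsBridson(mask, 1L, radius = 3, rngSeed = 12)
  expect_false(identical(seedPoints(s1), seedPoints(s3)))
})

test_that("Voronoi assignment matches the exhaustive nearest-seed scan", {
  mask <- boxMask(c(20L, 20L, 20L))
  for (seed in 1:3) {
    s <- sampleSeedsBridson(mask, 2L, radius = 2.5, rngSeed = seed)
    part <- assignVoronoi(mask, 2L, s)
    brute <- bruteVoronoi(mask, 2L, seedPoints(s))
    expect_identical(length(subvolumeSizes(part)), nrow(seedPoints(s)))
    expect_identical(subvolumeLabels(part), brute)
  }

  # one seed -> a single subvolume covering the lung
  sOne <- sampleSeedsBridson(mask, 1L, radius = 60, rngSeed = 2)
  pOne <- assignVoronoi(mask, 1L, sOne)
  expect_identical(sum(subvolumeSizes(pOne)), sum(maskLabels(mask) == 1L))
  expect_identical(length(subvolumeSizes(pOne)), 1L)
})

test_that("equidistant voxels take the lowest seed index", {
  lab <- array(0L, c(9L, 5L, 5L))
  lab[2:8, 2:4, 2:4] <- 1L
  mask <- LungMask(lab, 2)
  pts <- rbind(c(2, 2, 2), c(6, 2, 2)) # symmetric about x = 4
  seeds <- new("SeedSet", points = pts, radius = 4, rngSeed = 1L,
               lungLabel = 1L)
  part <- assignVoronoi(mask, 1L, seeds)
  plab <- subvolumeLabels(part)
  expect_true(all(plab[5, 2:4, 2:4] == 1L)) # x index 4 (0-based) equidistant
  expect_true(all(plab[2:4, 2:4, 2:4][plab[2:4, 2:4, 2:4] > 0] == 1L))
  expect_true(all(plab[7:8, 2:4, 2:4] == 2L))
})

test_that("partition realizations are deterministic, exhaustive and distinct", {
  mask <- boxMask()
  p1 <- partitionRealizations(mask, radius = 3, nRealizations = 3,
                              baseSeed = 100)
  p2 <- partitionRealizations(mask, radius = 3, nRealizations = 3,
                              baseSeed = 100)
  expect_length(p1, 3L)
  for (k in 1:3) {
    expect_identical(subvolumeLabels(p1[[k]]$left),
                     subvolumeLabels(p2[[k]]$left))
    for (lung in c("left", "right")) {
      part <- p1[[k]][[lung]]
      lungLab <- if (lung == "left") 1L else 2L
      # labels partition the lung exactly
      expect_identical(sum(subvolumeSizes(part)),
                       sum(maskLabels(mask) == lungLab))
      expect_true(all((subvolumeLabels(part) > 0) ==
                        (maskLabels(mask) == lungLab)))
      expect_identical(
        as.integer(tabulate(subvolumeLabels(part)[subvolumeLabels(part) > 0])),
        subvolumeSizes(part))
    }
  }
  # different realizations differ
  expect_false(identical(subvolumeLabels(p1[[1]]$left),
                         subvolumeLabels(p1[[2]]$left)))
  expect_length(partitionRealizations(mask, 3, 1, baseSeed = 1), 1L)
})

test_that("mean subvolume count: limits and monotonicity in the radius", {
  mask <- boxMask()
  # radius beyond both lungs -> one subvolume per lung
  expect_equal(meanSubvolumeCount(mask, radius = 60, nRealizations = 2,
                                  baseSeed = 4), 2)
  # single realization equals the K of that partition
  p <- partitionRealizations(mask, 4, 1, baseSeed = 9)[[1]]
  expect_equal(meanSubvolumeCount(mask, 4, 1, baseSeed = 9),
               length(subvolumeSizes(p$left)) +
                 length(subvolumeSizes(p$right)))
  # packing: more seeds fit at r = 3 than at r = 8, for several base seeds
  for (bs in 1:5) {
    expect_gte(meanSubvolumeCount(mask, 3, 2, baseSeed = bs),
               meanSubvolumeCount(mask, 8, 2, baseSeed = bs))
  }
})
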