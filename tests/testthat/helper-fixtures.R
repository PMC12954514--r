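# Shared fixtures: tiny deterministic masks/grids built in code.

# Two rectangular "lungs" in a small grid: quick and fully controlled.
boxMask <- function(shape = c(16L, 16L, 16L), spacing = 2) {
  lab <- array(0L, shape)
  lab[3:7, 4:13, 4:13] <- 1L
  lab[10:14, 4:13, 4:13] <- 2L
  LungMask(lab, spacing)
}

# Two-ellipsoid mask with configurable size (no jitter).
ellipsoidMask <- function(shape = c(40L, 40L, 40L), spacing = 2) {
  cfg <- cohortConfig(nCases = 4, gridShape = shape, isoMm = spacing,
                      lungCenters = list(left = shape * c(0.32, 0.5, 0.5),
                                         right = shape * c(0.68, 0.5, 0.5)),
                      lungSemiAxes = shape * c(0.155, 0.2, 0.34),
                      centerJitterSd = 0, axisJitterSd = 0)
  makeLungMask(cfg, rngSeed = 1)
}

# Positive random intensities on the grid of a mask.
randomGrid <- function(mask, seed = 1) {
  set.seed(seed)
  d <- dim(maskLabels(mask))
  VolumeGrid(array(stats::rexp(prod(d)) + 0.05, d), voxelSpacing(mask))
}

# Independent nearest-seed scan: label every lung voxel with the index of
# its closest seed (ties -> lowest index via which.min).
bruteVoronoi <- function(mask, lungLabel, pts) {
  lab <- maskLabels(mask)
  d <- dim(lab)
  out <- array(0L, d)
  idx <- which(lab == lungLabel)
  co <- arrayInd(idx, d) - 1L # voxel centre = 0-based index
  for (v in seq_along(idx)) {
    dd <- (pts[, 1] - co[v, 1])^2 + (pts[, 2] - co[v, 2])^2 +
      (pts[, 3] - co[v, 3])^2
    out[idx[v]] <- which.min(dd)
  }
  out
}

# Independent brute-force descriptive statistics (plain textbook formulas).
oracleQuantile <- function(x, p) unname(quantile(x, p, type = 7))
oracleStats <- function(x, metric) {
  n <- length(x)
  switch(metric,
    MIN = min(x), MAX = max(x),
    MEDIAN = oracleQuantile(x, 0.5),
    MEAN = sum(x) / n,
    COV = {
      med <- oracleQuantile(x, 0.5)
      if (med == 0) NA_real_ else sqrt(sum((x - mean(x))^2) / n) / med
    },
    P25 = oracleQuantile(x, 0.25), P75 = oracleQuantile(x, 0.75),
    SKEWNESS = {
      m <- mean(x)
      m2 <- sum((x - m)^2) / n
      if (m2 == 0) 0 else (sum((x - m)^3) / n) / m2^1.5
    },
    MODE_OVER_MEDIAN = {
      med <- oracleQuantile(x, 0.5)
      if (med == 0) return(NA_real_)
      lo <- min(x); hi <- max(x)
      mode <- if (lo == hi) lo else {
        w <- (hi - lo) / 64
        b <- pmin(floor((x - lo) / w) + 1, 64)
        k <- which.max(tabulate(b, 64))
        lo + (k - 0.5) * w
      }
      mode / med
    })
}
oraclePn <- function(v, w, N) {
  cutoff <- (N / 100) * max(v)
  s <- 0
  tot <- 0
  for (i in seq_along(v)) { # explicit loop: independent of vector code path
    if (v[i] <= cutoff) s <- s + w[i]
    tot <- tot + w[i]
  }
  100 * s / tot
}

# Independent LOOCV logistic regression via per-fold glm refits.
oracleLoocvProbs <- function(X, y) {
  n <- nrow(X)
  vapply(seq_len(n), function(i) {
    tr <- setdiff(seq_len(n), i)
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, sd)
    sdv[sdv <= 0] <- 1
    Xtr <- scale(X[tr, , drop = FALSE], center = mu, scale = sdv)
    Xte <- (X[i, ] - mu) / sdv
    df <- data.frame(y = y[tr], Xtr)
    fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    eta <- coef(fit)[1] + sum(coef(fit)[-1] * Xte)
    1 / (1 + exp(-eta))
  }, numeric(1))
}

oracleAucU <- function(prob, y) {
  # Mann-Whitney U normalization
  r <- rank(prob)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
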