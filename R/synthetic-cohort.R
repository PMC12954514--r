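# Run code under a fixed seed, restoring the caller's RNG state afterwards.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic cohort configuration
#'
#' Defines the generative model for fully self-contained test cohorts:
#' jittered two-ellipsoid lung masks, smooth positive perfusion fields
#' (exponentiated blurred Gaussian noise, median about 1) with spherical
#' hypoperfused defects multiplied in, and PFT values decreasing in total
#' defect burden with Gaussian noise. Defaults emulate a modest clinical
#' perfusion cohort: 36 cases on a 64^3 grid at 2 mm isotropic spacing, with
#' 3/36 of cases missing DLCO.
#'
#' @param nCases number of cases (>= 4).
#' @param gridShape 3D grid shape.
#' @param isoMm isotropic voxel spacing in mm.
#' @param lungCenters list of left/right ellipsoid centres (voxel units).
#' @param lungSemiAxes semi-axes in voxels, shared by both lungs.
#' @param centerJitterSd sd of the per-case centre jitter (voxels).
#' @param axisJitterSd sd of the per-case log semi-axis jitter.
#' @param blurSd Gaussian blur sd of the base field, in voxels.
#' @param fieldLogSd log-scale sd of the base field heterogeneity.
#' @param defectRadiusRange min/max defect sphere radius (voxels).
#' @param defectMultiplier intensity multiplier inside defects, in [0, 1).
#' @param defectFractionRange per-lung defect volume fraction is drawn
#'   uniformly from this range (within [0, 0.6]).
#' @param pftCoupling per-measure \code{c(intercept, slope, noiseSd)}:
#'   value = intercept - slope * totalDefectFraction + noise, truncated at 0.
#'   Default slopes/noise put the defect-to-FEV1 Spearman magnitude near 0.9
#'   and make roughly a third of cases abnormal under the 60/70/70 rule.
#' @param dlcoMissingFrac fraction of cases with DLCO missing.
#' @param masterSeed integer; case i uses the substream masterSeed + i.
#' @return A list of class \code{"voroperfCohortConfig"}.
#' @export
cohortConfig <- function(nCases = 36L, gridShape = c(64L, 64L, 64L),
                         isoMm = 2.0,
                         lungCenters = list(left = c(21, 32, 32),
                                            right = c(43, 32, 32)),
                         lungSemiAxes = c(10, 13, 22),
                         centerJitterSd = 1.0, axisJitterSd = 0.05,
                         blurSd = 3.0, fieldLogSd = 0.25,
                         defectRadiusRange = c(2, 5),
                         defectMultiplier = 0.25,
                         defectFractionRange = c(0, 0.5),
                         pftCoupling = list(
                           dlco_pct = c(intercept = 95, slope = 90,
                                        noiseSd = 6),
                           fev1_pct = c(intercept = 105, slope = 100,
                                        noiseSd = 5),
                           fvc_pct = c(intercept = 100, slope = 60,
                                       noiseSd = 8),
                           fev1_fvc = c(intercept = 85, slope = 45,
                                        noiseSd = 4)),
                         dlcoMissingFrac = 3 / 36, masterSeed = 1L) {
  if (nCases < 4L) stop("config error: nCases must be >= 4")
  if (defectMultiplier < 0 || defectMultiplier >= 1)
    stop("config error: defectMultiplier must be in [0, 1)")
  if (any(defectFractionRange < 0) || any(defectFractionRange > 0.6))
    stop("config error: defect fractions must lie in [0, 0.6]")
  for (cp in pftCoupling)
    if (cp[["noiseSd"]] < 0) stop("config error: negative noise sd")
  halfSpan <- lungSemiAxes * 1.2 # room for jitter
  fits <- vapply(lungCenters, function(ctr)
    all(ctr - halfSpan >= 1) && all(ctr + halfSpan <= gridShape),
    logical(1))
  if (!all(fits))
    stop("config error: lung semi-axes do not fit inside the grid")
  structure(list(nCases = as.integer(nCases), gridShape = gridShape,
                 isoMm = isoMm, lungCenters = lungCenters,
                 lungSemiAxes = lungSemiAxes,
                 centerJitterSd = centerJitterSd,
                 axisJitterSd = axisJitterSd, blurSd = blurSd,
                 fieldLogSd = fieldLogSd,
                 defectRadiusRange = defectRadiusRange,
                 defectMultiplier = defectMultiplier,
                 defectFractionRange = defectFractionRange,
                 pftCoupling = pftCoupling,
                 dlcoMissingFrac = dlcoMissingFrac,
                 masterSeed = as.integer(masterSeed)),
            class = "voroperfCohortConfig")
}

# Separable Gaussian blur with edge renormalization (each output voxel is a
# properly normalized average of its in-grid neighbourhood).
.gaussianBlur3d <- function(arr, sd) {
  blur1 <- function(n) {
    K <- outer(seq_len(n), seq_len(n),
               function(i, j) exp(-((i - j)^2) / (2 * sd^2)))
    K / rowSums(K)
  }
  d <- dim(arr)
  m <- blur1(d[1]) %*% matrix(arr, d[1])
  dim(m) <- d
  m <- aperm(m, c(2, 3, 1))
  m2 <- blur1(d[2]) %*% matrix(m, d[2])
  dim(m2) <- d[c(2, 3, 1)]
  m2 <- aperm(m2, c(2, 3, 1))
  m3 <- blur1(d[3]) %*% matrix(m2, d[3])
  dim(m3) <- d[c(3, 1, 2)]
  aperm(m3, c(2, 3, 1))
}

.voxelizeEllipsoid <- function(gridShape, center, semi) {
  nx <- gridShape[1]; ny <- gridShape[2]; nz <- gridShape[3]
  dx2 <- ((seq_len(nx) - 1 - center[1]) / semi[1])^2
  dy2 <- ((seq_len(ny) - 1 - center[2]) / semi[2])^2
  dz2 <- ((seq_len(nz) - 1 - center[3]) / semi[3])^2
  q <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  q <= 1
}

#' Generate a two-lobed synthetic lung mask
#'
#' Two disjoint jittered ellipsoids, labelled 1 (left) and 2 (right); if the
#' jittered ellipsoids overlap the draw is retried (bounded) before failing.
#' With zero jitter the mask is the exact voxelization of the configured
#' ellipsoid equations.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param rngSeed integer seed for the jitter.
#' @return A \linkS4class{LungMask}.
#' @export
makeLungMask <- function(config, rngSeed) {
  .withSeed(rngSeed, {
    for (try in 1:10) {
      l <- .voxelizeEllipsoid(
        config$gridShape,
        config$lungCenters$left + rnorm(3, 0, config$centerJitterSd),
        config$lungSemiAxes * exp(rnorm(3, 0, config$axisJitterSd)))
      r <- .voxelizeEllipsoid(
        config$gridShape,
        config$lungCenters$right + rnorm(3, 0, config$centerJitterSd),
        config$lungSemiAxes * exp(rnorm(3, 0, config$axisJitterSd)))
      if (!any(l & r) && any(l) && any(r)) {
        lab <- array(0L, config$gridShape)
        lab[l] <- 1L
        lab[r] <- 2L
        return(LungMask(lab, config$isoMm))
      }
    }
    stop("could not place disjoint lungs after 10 jitter draws")
  })
}

# Insert spherical defect regions into one lung until the requested in-lung
# volume fraction is covered; returns the updated defect indicator.
.insertDefects <- function(defect, lungSel, targetFraction, config) {
  nLung <- sum(lungSel)
  idxLung <- which(lungSel)
  d <- dim(lungSel)
  coords <- arrayInd(idxLung, d)
  attempts <- 0L
  while (sum(defect[idxLung]) / nLung < targetFraction) {
    attempts <- attempts + 1L
    if (attempts > 5000L)
      stop("config error: defect fraction ", targetFraction,
           " unreachable with configured radii")
    ctr <- coords[sample.int(nrow(coords), 1L), ]
    rad <- runif(1, config$defectRadiusRange[1], config$defectRadiusRange[2])
    lo <- pmax(ctr - ceiling(rad), 1)
    hi <- pmin(ctr + ceiling(rad), d)
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    q <- outer(outer((xs - ctr[1])^2, (ys - ctr[2])^2, `+`),
               (zs - ctr[3])^2, `+`)
    sph <- which(q <= rad^2, arr.ind = TRUE)
    ii <- cbind(xs[sph[, 1]], ys[sph[, 2]], zs[sph[, 3]])
    inside <- lungSel[ii]
    defect[ii[inside, , drop = FALSE]] <- TRUE
  }
  defect
}

#' Generate a raw-valued synthetic perfusion map
#'
#' The base field is a positive smooth heterogeneous field: white Gaussian
#' noise blurred with a separable Gaussian, standardized, and exponentiated
#' (log-sd \code{fieldLogSd}), so values are strictly positive with median
#' about 1. Spherical defect regions are inserted per lung until the
#' requested in-lung volume fraction is covered, and the intensities inside
#' them are multiplied by \code{defectMultiplier} (defects multiply rather
#' than replace, so percentile maps remain informative). The achieved
#' fractions are recorded in the \code{"defectFraction"} attribute.
#'
#' @param mask a \linkS4class{LungMask}.
#' @param defectFractionLeft,defectFractionRight requested in-lung defect
#'   volume fractions, each in [0, 0.6].
#' @param config a \code{\link{cohortConfig}}.
#' @param rngSeed integer seed.
#' @return A \linkS4class{VolumeGrid} with attribute \code{"defectFraction"}
#'   (named numeric, achieved left/right fractions).
#' @export
makePerfusionMap <- function(mask, defectFractionLeft, defectFractionRight,
                             config, rngSeed) {
  if (defectFractionLeft < 0 || defectFractionLeft > 0.6 ||
      defectFractionRight < 0 || defectFractionRight > 0.6)
    stop("defect fractions must lie in [0, 0.6]")
  .withSeed(rngSeed, {
    d <- dim(mask@labels)
    z <- .gaussianBlur3d(array(rnorm(prod(d)), d), config$blurSd)
    z <- (z - mean(z)) / sd(z)
    vals <- exp(config$fieldLogSd * z)
    defect <- array(FALSE, d)
    defect <- .insertDefects(defect, mask@labels == 1L, defectFractionLeft,
                             config)
    defect <- .insertDefects(defect, mask@labels == 2L, defectFractionRight,
                             config)
    vals[defect] <- vals[defect] * config$defectMultiplier
    achieved <- c(
      left = sum(defect[mask@labels == 1L]) / sum(mask@labels == 1L),
      right = sum(defect[mask@labels == 2L]) / sum(mask@labels == 2L))
    out <- VolumeGrid(vals, mask@spacing)
    attr(out, "defectFraction") <- achieved
    out
  })
}

#' Generate a synthetic cohort with PFTs coupled to defect burden
#'
#' Per case (substream \code{masterSeed + i}): a jittered lung mask, per-lung
#' defect fractions drawn uniformly from \code{defectFractionRange}, a
#' perfusion map with those defects, and PFT values
#' \code{intercept - slope * totalDefectFraction + noise} truncated at 0,
#' where the total fraction is the lung-volume-weighted mean of the achieved
#' per-lung fractions. DLCO is set missing for \code{dlcoMissingFrac} of
#' cases. Ground-truth fractions are retained for recovery tests.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return A list with \code{cases} (each: \code{caseId}, \code{grid},
#'   \code{mask}), \code{pft} (data.frame), and \code{truth} (data.frame
#'   with the achieved defect fractions).
#' @export
makeCohort <- function(config) {
  n <- config$nCases
  cases <- vector("list", n)
  truth <- data.frame(case_id = sprintf("case%03d", seq_len(n)),
                      defect_left = NA_real_, defect_right = NA_real_,
                      defect_total = NA_real_, stringsAsFactors = FALSE)
  pft <- data.frame(case_id = truth$case_id, dlco_pct = NA_real_,
                    fev1_pct = NA_real_, fvc_pct = NA_real_,
                    fev1_fvc = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    seed_i <- config$masterSeed + i
    mask <- makeLungMask(config, seed_i)
    fr <- .withSeed(seed_i + 500000L,
                    runif(2, config$defectFractionRange[1],
                          config$defectFractionRange[2]))
    grid <- makePerfusionMap(mask, fr[1], fr[2], config, seed_i + 1000000L)
    ach <- attr(grid, "defectFraction")
    nl <- sum(mask@labels == 1L)
    nr <- sum(mask@labels == 2L)
    dTot <- (ach[["left"]] * nl + ach[["right"]] * nr) / (nl + nr)
    truth[i, 2:4] <- c(ach[["left"]], ach[["right"]], dTot)
    vals <- .withSeed(seed_i + 1500000L, vapply(
      c("dlco_pct", "fev1_pct", "fvc_pct", "fev1_fvc"), function(meas) {
        cp <- config$pftCoupling[[meas]]
        max(0, cp[["intercept"]] - cp[["slope"]] * dTot +
              rnorm(1, 0, cp[["noiseSd"]]))
      }, numeric(1)))
    pft[i, 2:5] <- vals
    cases[[i]] <- list(caseId = truth$case_id[i], grid = grid, mask = mask)
  }
  nMiss <- round(n * config$dlcoMissingFrac)
  if (nMiss > 0) {
    miss <- .withSeed(config$masterSeed + 2000000L, sample.int(n, nMiss))
    pft$dlco_pct[miss] <- NA_real_
  }
  list(cases = cases, pft = pft, truth = truth)
}

#' Write / read a cohort in the standard case layout
#'
#' Each case gets a directory \code{<case_id>/} holding
#' \code{perfusion.nii.gz} and \code{lungs.nii.gz}; the cohort root holds
#' \code{pft.csv} and (when available) \code{truth.csv}.
#'
#' @param cohort list from \code{\link{makeCohort}}.
#' @param dir output directory (created if needed).
#' @return \code{writeCohort}: \code{dir}, invisibly; \code{readCohort}: a
#'   cohort list (without \code{truth} if absent on disk).
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cs in cohort$cases) {
    cdir <- file.path(dir, cs$caseId)
    dir.create(cdir, showWarnings = FALSE)
    writeCase(cs$grid, cs$mask, file.path(cdir, "perfusion.nii.gz"),
              file.path(cdir, "lungs.nii.gz"))
  }
  # full-precision numeric formatting so a disk round trip is value-exact
  fullPrec <- function(df) {
    for (col in names(df))
      if (is.numeric(df[[col]]))
        df[[col]] <- ifelse(is.na(df[[col]]), "",
                            sprintf("%.17g", df[[col]]))
    df
  }
  write.csv(fullPrec(cohort$pft), file.path(dir, "pft.csv"),
            row.names = FALSE)
  if (!is.null(cohort$truth))
    write.csv(fullPrec(cohort$truth), file.path(dir, "truth.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  pft <- readPftTable(file.path(dir, "pft.csv"))
  cases <- lapply(pft$case_id, function(id) {
    cdir <- file.path(dir, id)
    cs <- readCase(file.path(cdir, "perfusion.nii.gz"),
                   file.path(cdir, "lungs.nii.gz"))
    list(caseId = id, grid = cs$grid, mask = cs$mask)
  })
  truthPath <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truthPath))
    read.csv(truthPath, stringsAsFactors = FALSE) else NULL
  list(cases = cases, pft = pft, truth = truth)
}
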