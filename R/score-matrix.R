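#' Pipeline run configuration
#'
#' Bundles the grids and seeds of the brute-force metric search. The
#' \code{"full"} preset follows the study protocol at full fidelity (radius
#' grid 10..90 step 1, N grid 5..95 step 0.1, five seed realizations); the
#' \code{"coarse"} preset (radius step 10, N step 5, two realizations) keeps
#' the complete protocol cheap enough for routine regression runs.
#'
#' @param preset \code{"coarse"} or \code{"full"}.
#' @param radii Voronoi radius grid (isotropic-voxel units); overrides the
#'   preset.
#' @param nGrid N-threshold grid for \code{P_N}, in percent within [5, 95].
#' @param scenarios subset of the four processing scenarios.
#' @param valueKinds subset of \code{c("raw", "percentile")}.
#' @param nRealizations seed realizations per radius.
#' @param baseSeed integer; all geometry randomness derives from it.
#' @param kAttempts Bridson candidate attempts per active point.
#' @param isoMm working isotropic spacing in mm.
#' @param topK ranked metrics retained per PFT measure.
#' @param maxSubsetSize,maxSubsets caps for the best-subset covariate search.
#' @param thresholds named abnormality cutoffs (\code{dlco}, \code{fev1},
#'   \code{fev1_fvc}), in the units of the PFT table.
#' @return A list of class \code{"voroperfConfig"}.
#' @export
runConfig <- function(preset = c("coarse", "full"), radii = NULL,
                      nGrid = NULL, scenarios = .SCENARIOS,
                      valueKinds = c("raw", "percentile"),
                      nRealizations = NULL, baseSeed = 1L, kAttempts = 30L,
                      isoMm = 2.0, topK = 5L, maxSubsetSize = NULL,
                      maxSubsets = 2^15 - 1,
                      thresholds = c(dlco = 60, fev1 = 70, fev1_fvc = 70)) {
  preset <- match.arg(preset)
  if (is.null(radii))
    radii <- if (preset == "coarse") seq(10, 90, by = 10) else seq(10, 90)
  if (is.null(nGrid))
    nGrid <- if (preset == "coarse") seq(5, 95, by = 5) else
      seq(5, 95, by = 0.1)
  if (is.null(nRealizations))
    nRealizations <- if (preset == "coarse") 2L else 5L
  if (!length(radii) || !length(nGrid)) stop("config error: empty grid")
  if (any(nGrid < 5 | nGrid > 95)) stop("config error: N grid outside [5, 95]")
  scenarios <- intersect(.SCENARIOS, scenarios)
  if (!length(scenarios)) stop("config error: no scenarios")
  valueKinds <- intersect(.VALUE_KINDS, valueKinds)
  if (!length(valueKinds)) stop("config error: no value kinds")
  if (nRealizations < 1L) stop("config error: nRealizations must be >= 1")
  structure(list(preset = preset, radii = radii, nGrid = nGrid,
                 scenarios = scenarios, valueKinds = valueKinds,
                 nRealizations = as.integer(nRealizations),
                 baseSeed = as.integer(baseSeed),
                 kAttempts = as.integer(kAttempts), isoMm = isoMm,
                 topK = as.integer(topK),
                 maxSubsetSize = if (is.null(maxSubsetSize)) NA_integer_ else
                   as.integer(maxSubsetSize),
                 maxSubsets = maxSubsets, thresholds = thresholds),
            class = "voroperfConfig")
}

#' Seed used for the partitions of one (case, radius) pair
#'
#' All geometry randomness flows from the configured base seed: case i
#' (1-based) at radius index j uses \code{baseSeed + (i-1)*1000000 +
#' (j-1)*1000}, and realization k adds k (the right lung draws from a
#' stream offset by 500000 inside \code{\link{partitionRealizations}}).
#' Exposed so single scores can be recomputed outside the matrix sweep.
#'
#' @param baseSeed configured base seed.
#' @param caseIndex 1-based index of the case in the cohort.
#' @param radiusIndex 1-based index into the radius grid.
#' @return An integer seed.
#' @export
partitionSeed <- function(baseSeed, caseIndex, radiusIndex) {
  as.integer(baseSeed + (caseIndex - 1L) * 1000000L +
               (radiusIndex - 1L) * 1000L)
}

# id strings for one (scenario, radius, intra, lr, kind) block, vectorized
# over the inter-statistic keys.
.idsForInter <- function(scenario, radius, intra, interKeys, lr, kind) {
  isPn <- startsWith(interKeys, "P_N@")
  inter <- ifelse(isPn, "P_N", interKeys)
  nStr <- ifelse(isPn, substring(interKeys, 5L), "-")
  paste(scenario, .fmtNum(radius), if (is.na(intra)) "-" else intra, inter,
        nStr, if (is.na(lr)) "-" else lr, kind, sep = "|")
}

#' Enumerate the MetricSpec search space
#'
#' Yields every consistent combination the configured grids admit: Full
#' scenarios carry no radius or intra-subvolume metric; L+R scenarios no
#' left-right operator; \code{P_N} expands over the N grid. The row count
#' equals the closed-form product of the option cardinalities.
#'
#' @param config a \code{\link{runConfig}}.
#' @return A data.frame with columns \code{scenario}, \code{radius},
#'   \code{intraMetric}, \code{interMetric}, \code{nThreshold},
#'   \code{lrMetric}, \code{valueKind} and the canonical \code{id} string
#'   (see \code{\link{specId}}).
#' @export
enumerateSpecs <- function(config) {
  ng <- config$nGrid
  interMetric <- c(rep("P_N", length(ng)), "COV", "MODE_OVER_MEDIAN",
                   "MEDIAN", "P25", "P75", "SKEWNESS")
  nThreshold <- c(ng, rep(NA_real_, 6L))
  blocks <- list()
  for (kind in config$valueKinds) {
    for (sc in config$scenarios) {
      voronoi <- sc %in% c("VORONOI_LR_TOGETHER", "VORONOI_LR_SPLIT")
      splitLR <- sc %in% c("FULL_LR_SPLIT", "VORONOI_LR_SPLIT")
      g <- expand.grid(
        interIdx = seq_along(interMetric),
        radius = if (voronoi) config$radii else NA_real_,
        intraMetric = if (voronoi) .INTRA_METRICS else NA_character_,
        lrMetric = if (splitLR) .LR_METRICS else NA_character_,
        stringsAsFactors = FALSE)
      blocks[[length(blocks) + 1L]] <- data.frame(
        scenario = sc, radius = g$radius, intraMetric = g$intraMetric,
        interMetric = interMetric[g$interIdx],
        nThreshold = nThreshold[g$interIdx], lrMetric = g$lrMetric,
        valueKind = kind, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, blocks)
  nStr <- ifelse(is.na(out$nThreshold), "-", .fmtNum(out$nThreshold))
  out$id <- paste(out$scenario, .fmtNum(out$radius),
                  ifelse(is.na(out$intraMetric), "-", out$intraMetric),
                  out$interMetric, nStr,
                  ifelse(is.na(out$lrMetric), "-", out$lrMetric),
                  out$valueKind, sep = "|")
  rownames(out) <- NULL
  out
}

# Vectorized left-right combination over a vector of per-lung summaries;
# mirrors lrCombine element-wise (including NA poisoning on either side).
.lrCombineVec <- function(l, r, nl, nr, perfL, perfR, op) {
  out <- switch(op,
    MIN = pmin(l, r),
    MAX = pmax(l, r),
    AVG = (l + r) / 2,
    VOL_WEIGHTED_AVG = (l * nl + r * nr) / (nl + nr),
    PERF_WEIGHTED_AVG = if (perfL + perfR == 0)
      rep(NA_real_, length(l)) else (l * perfL + r * perfR) / (perfL + perfR),
    LARGEST_VOL = if (nl >= nr) l else r,
    SMALLEST_VOL = if (nl <= nr) l else r,
    MOST_PERF = if (perfL >= perfR) l else r,
    LEAST_PERF = if (perfL <= perfR) l else r)
  out[is.na(l) | is.na(r)] <- NA_real_
  out
}

# All configured spec scores for one case, as a named vector keyed by spec
# id. Intra-level values are computed once per (radius, realization,
# subvolume) and reused across the inter/LR sweeps; results are bit-identical
# to globalScore() because both routes share the same primitives.
.scoreCaseAll <- function(grid, mask, config, caseIndex, buildNames = TRUE) {
  mlab <- mask@labels
  nl <- sum(mlab == 1L)
  nr <- sum(mlab == 2L)
  ng <- config$nGrid
  interKeys <- c(.pnKeys(ng),
                 c("COV", "MODE_OVER_MEDIAN", "MEDIAN", "P25", "P75",
                   "SKEWNESS"))
  scen <- config$scenarios
  needVoronoi <- any(c("VORONOI_LR_TOGETHER", "VORONOI_LR_SPLIT") %in% scen)
  partitions <- NULL
  if (needVoronoi)
    partitions <- lapply(seq_along(config$radii), function(j) {
      partitionRealizations(mask, config$radii[j], config$nRealizations,
                            partitionSeed(config$baseSeed, caseIndex, j),
                            config$kAttempts)
    })
  acc <- list()
  push <- function(vals, ids) {
    if (buildNames) names(vals) <- ids # ids is lazy; never forced otherwise
    acc[[length(acc) + 1L]] <<- vals
  }
  for (kind in config$valueKinds) {
    map <- if (kind == "percentile") toPercentileMap(grid, mask) else grid
    vals <- map@values
    pooled <- vals[mlab > 0L]
    vl <- vals[mlab == 1L]
    vr <- vals[mlab == 2L]
    perfL <- sum(vl)
    perfR <- sum(vr)
    if ("FULL_LR_TOGETHER" %in% scen)
      push(.interAll(pooled, rep(1, length(pooled)), ng, interKeys),
           .idsForInter("FULL_LR_TOGETHER", NA, NA, interKeys, NA, kind))
    if ("FULL_LR_SPLIT" %in% scen) {
      il <- .interAll(vl, rep(1, nl), ng, interKeys)
      ir <- .interAll(vr, rep(1, nr), ng, interKeys)
      for (op in .LR_METRICS)
        push(.lrCombineVec(il, ir, nl, nr, perfL, perfR, op),
             .idsForInter("FULL_LR_SPLIT", NA, NA, interKeys, op, kind))
    }
    if (needVoronoi) {
      nk <- config$nRealizations
      for (j in seq_along(config$radii)) {
        r <- config$radii[j]
        parts <- partitions[[j]]
        # 9 intra metrics x K subvolumes, per lung and realization
        intraL <- lapply(parts, function(p) .intraMatrix(vals, p$left))
        intraR <- lapply(parts, function(p) .intraMatrix(vals, p$right))
        sizesL <- lapply(parts, function(p) p$left@sizes)
        sizesR <- lapply(parts, function(p) p$right@sizes)
        for (m in .INTRA_METRICS) {
          if ("VORONOI_LR_TOGETHER" %in% scen) {
            tog <- vapply(seq_len(nk), function(k)
              .interAll(c(intraL[[k]][m, ], intraR[[k]][m, ]),
                        c(as.numeric(sizesL[[k]]), as.numeric(sizesR[[k]])),
                        ng, interKeys), numeric(length(interKeys)))
            push(rowSums(tog) / nk,
                 .idsForInter("VORONOI_LR_TOGETHER", r, m, interKeys, NA,
                              kind))
          }
          if ("VORONOI_LR_SPLIT" %in% scen) {
            iL <- vapply(seq_len(nk), function(k)
              .interAll(intraL[[k]][m, ], as.numeric(sizesL[[k]]), ng,
                        interKeys), numeric(length(interKeys)))
            iR <- vapply(seq_len(nk), function(k)
              .interAll(intraR[[k]][m, ], as.numeric(sizesR[[k]]), ng,
                        interKeys), numeric(length(interKeys)))
            for (op in .LR_METRICS) {
              comb <- vapply(seq_len(nk), function(k)
                .lrCombineVec(iL[, k], iR[, k], nl, nr, perfL, perfR, op),
                numeric(length(interKeys)))
              push(rowSums(comb) / nk,
                   .idsForInter("VORONOI_LR_SPLIT", r, m, interKeys, op,
                                kind))
            }
          }
        }
      }
    }
  }
  res <- unlist(acc, use.names = TRUE)
  res
}

#' Score a cohort against the whole metric search space
#'
#' Computes the global perfusion score of every case for every
#' \linkS4class{MetricSpec} the configuration enumerates. Intra-subvolume
#' values are computed once per (case, radius, realization) and reused across
#' the inter/left-right sweeps; entries are bit-identical to calling
#' \code{\link{globalScore}} spec by spec with the partitions of
#' \code{\link{partitionSeed}}.
#'
#' @param cohort list of cases; each case is a list with elements
#'   \code{caseId}, \code{grid} (\linkS4class{VolumeGrid}) and \code{mask}
#'   (\linkS4class{LungMask}).
#' @param config a \code{\link{runConfig}}.
#' @param verbose log per-case progress.
#' @return Numeric matrix, rows = cases (rownames = case ids), columns =
#'   canonical spec id strings, with the enumeration data.frame attached as
#'   attribute \code{"specs"}.
#' @export
scoreCohort <- function(cohort, config, verbose = FALSE) {
  specs <- enumerateSpecs(config)
  ids <- specs$id
  caseIds <- vapply(cohort, function(cs) cs$caseId, character(1))
  M <- matrix(NA_real_, length(cohort), length(ids),
              dimnames = list(caseIds, ids))
  perm <- NULL
  for (i in seq_along(cohort)) {
    t0 <- proc.time()[["elapsed"]]
    # names are built once (the block layout is config-determined, so the
    # value order is identical for every case)
    v <- .scoreCaseAll(cohort[[i]]$grid, cohort[[i]]$mask, config, i,
                       buildNames = is.null(perm))
    if (is.null(perm)) {
      perm <- match(ids, names(v))
      if (anyNA(perm)) stop("internal error: spec enumeration mismatch")
    }
    M[i, ] <- v[perm]
    if (verbose)
      message(sprintf("scored case %s (%d/%d) in %.1f s", caseIds[i], i,
                      length(cohort), proc.time()[["elapsed"]] - t0))
  }
  attr(M, "specs") <- specs
  M
}

#' Write / read a score matrix as CSV
#'
#' Rows are cases, columns are canonical MetricSpec identifier strings.
#'
#' @param scores matrix from \code{\link{scoreCohort}}.
#' @param path CSV path.
#' @return \code{writeScoreMatrix}: the path, invisibly;
#'   \code{readScoreMatrix}: the matrix (without the \code{"specs"}
#'   attribute).
#' @export
writeScoreMatrix <- function(scores, path) {
  df <- data.frame(case_id = rownames(scores), scores, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScoreMatrix
#' @export
readScoreMatrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$case_id
  m
}
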