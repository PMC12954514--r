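#' @import methods
#' @importFrom stats median quantile rnorm runif sd var cor pt lm.fit
#' @importFrom utils read.csv write.csv head tail
#' @importFrom Rcpp sourceCpp
#' @useDynLib voroperf, .registration = TRUE
NULL

#' VolumeGrid: a 3D scalar field with voxel spacing
#'
#' Carrier for perfusion maps: a 3D array of scalar intensities (arbitrary
#' units for raw maps, or per-lung percentiles in (0,1]) together with the
#' physical voxel spacing in millimetres.
#'
#' @slot values 3D numeric array.
#' @slot spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @export
setClass("VolumeGrid",
  representation(values = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
      msg <- c(msg, "values must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be three strictly positive numbers")
    if (length(msg)) msg else TRUE
  })

#' LungMask: left/right lung labels on a voxel grid
#'
#' Integer label volume co-registered with a \linkS4class{VolumeGrid}:
#' 0 = background, 1 = left lung, 2 = right lung.
#'
#' @slot labels 3D integer array with values in \{0, 1, 2\}.
#' @slot spacing numeric length-3, mm per voxel; must match the paired grid.
#' @export
setClass("LungMask",
  representation(labels = "array", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3L)
      msg <- c(msg, "labels must be a 3D array")
    if (!all(object@labels %in% c(0L, 1L, 2L)))
      msg <- c(msg, "mask labels must be coded 0 (background), 1 (left), 2 (right)")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be three strictly positive numbers")
    if (length(msg)) msg else TRUE
  })

#' SeedSet: one Poisson-disk seed realization for one lung
#'
#' @slot points numeric matrix (n x 3) of continuous seed coordinates in
#'   isotropic-voxel units (the centre of voxel index i is i, 0-based).
#' @slot radius minimum pairwise spacing r, in isotropic-voxel units.
#' @slot rngSeed integer seed that generated this realization.
#' @slot lungLabel 1 (left) or 2 (right).
#' @export
setClass("SeedSet",
  representation(points = "matrix", radius = "numeric", rngSeed = "integer",
                 lungLabel = "integer"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@points) != 3L || nrow(object@points) < 1L)
      msg <- c(msg, "points must be a non-empty n x 3 matrix")
    if (!(object@lungLabel %in% c(1L, 2L)))
      msg <- c(msg, "lungLabel must be 1 or 2")
    if (object@radius <= 0) msg <- c(msg, "radius must be positive")
    if (length(msg)) msg else TRUE
  })

#' Partition: per-voxel Voronoi subvolume labelling of one lung
#'
#' @slot labels 3D integer array; 0 outside the lung, 1..K = subvolume id
#'   (1-based, in seed order).
#' @slot sizes integer vector of voxel counts per subvolume id.
#' @slot radius the seed spacing r that produced this partition.
#' @slot realization index of the seed realization (1-based).
#' @slot lungLabel 1 or 2.
#' @export
setClass("Partition",
  representation(labels = "array", sizes = "integer", radius = "numeric",
                 realization = "integer", lungLabel = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@sizes) < 1L || any(object@sizes <= 0L))
      msg <- c(msg, "every subvolume must be nonempty")
    if (sum(object@sizes) != sum(object@labels > 0L))
      msg <- c(msg, "subvolume sizes must sum to the lung voxel count")
    if (length(msg)) msg else TRUE
  })

.SCENARIOS <- c("FULL_LR_TOGETHER", "FULL_LR_SPLIT",
                "VORONOI_LR_TOGETHER", "VORONOI_LR_SPLIT")
.INTRA_METRICS <- c("MIN", "MAX", "MEDIAN", "MEAN", "COV", "P25", "P75",
                    "SKEWNESS", "MODE_OVER_MEDIAN")
.INTER_METRICS <- c("P_N", "COV", "MODE_OVER_MEDIAN", "MEDIAN", "P25", "P75",
                    "SKEWNESS")
.LR_METRICS <- c("MIN", "MAX", "AVG", "VOL_WEIGHTED_AVG", "PERF_WEIGHTED_AVG",
                 "LARGEST_VOL", "SMALLEST_VOL", "MOST_PERF", "LEAST_PERF")
.VALUE_KINDS <- c("raw", "percentile")

#' MetricSpec: one point in the hierarchical metric search space
#'
#' A scenario (whole-lung vs Voronoi-parcellated, lungs pooled vs split)
#' together with the radius, intra-subvolume metric, inter-subvolume metric
#' (and its N threshold for the defect-volume metric \code{P_N}), left-right
#' combination operator, and which map (raw or percentile) is scored.
#' Scenario determines exactly which optional fields are present; absent
#' fields are \code{NA}.
#'
#' @slot scenario one of FULL_LR_TOGETHER, FULL_LR_SPLIT, VORONOI_LR_TOGETHER,
#'   VORONOI_LR_SPLIT.
#' @slot radius seed spacing r in isotropic-voxel units (Voronoi scenarios only).
#' @slot intraMetric intra-subvolume statistic (Voronoi scenarios only).
#' @slot interMetric inter-subvolume statistic (always present).
#' @slot nThreshold N in percent, in [5, 95]; present iff interMetric == "P_N".
#' @slot lrMetric left-right combination operator (L/R scenarios only).
#' @slot valueKind "raw" or "percentile".
#' @export
setClass("MetricSpec",
  representation(scenario = "character", radius = "numeric",
                 intraMetric = "character", interMetric = "character",
                 nThreshold = "numeric", lrMetric = "character",
                 valueKind = "character"),
  validity = function(object) {
    msg <- character()
    sc <- object@scenario
    if (!(sc %in% .SCENARIOS)) msg <- c(msg, "unknown scenario")
    if (!(object@interMetric %in% .INTER_METRICS))
      msg <- c(msg, "unknown inter-subvolume metric")
    if (!(object@valueKind %in% .VALUE_KINDS))
      msg <- c(msg, "valueKind must be 'raw' or 'percentile'")
    voronoi <- sc %in% c("VORONOI_LR_TOGETHER", "VORONOI_LR_SPLIT")
    split <- sc %in% c("FULL_LR_SPLIT", "VORONOI_LR_SPLIT")
    if (voronoi) {
      if (is.na(object@radius) || object@radius < 1)
        msg <- c(msg, "Voronoi scenarios need radius >= 1")
      if (is.na(object@intraMetric) ||
          !(object@intraMetric %in% .INTRA_METRICS))
        msg <- c(msg, "Voronoi scenarios need a valid intra-subvolume metric")
    } else {
      if (!is.na(object@radius)) msg <- c(msg, "Full scenarios take no radius")
      if (!is.na(object@intraMetric))
        msg <- c(msg, "Full scenarios take no intra-subvolume metric")
    }
    if (split) {
      if (is.na(object@lrMetric) || !(object@lrMetric %in% .LR_METRICS))
        msg <- c(msg, "L/R scenarios need a valid left-right operator")
    } else if (!is.na(object@lrMetric)) {
      msg <- c(msg, "L+R scenarios take no left-right operator")
    }
    if (object@interMetric == "P_N") {
      if (is.na(object@nThreshold) || object@nThreshold < 5 ||
          object@nThreshold > 95)
        msg <- c(msg, "P_N needs an N threshold in [5, 95]")
    } else if (!is.na(object@nThreshold)) {
      msg <- c(msg, "nThreshold is only meaningful for P_N")
    }
    if (length(msg)) msg else TRUE
  })

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("VolumeGrid %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  v <- object@values[is.finite(object@values)]
  if (length(v))
    cat(sprintf("  values in [%.4g, %.4g]\n", min(v), max(v)))
})

setMethod("show", "LungMask", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LungMask %d x %d x %d: %d left, %d right lung voxels\n",
              d[1], d[2], d[3], sum(object@labels == 1L),
              sum(object@labels == 2L)))
})

setMethod("show", "SeedSet", function(object) {
  cat(sprintf("SeedSet: %d seeds, r = %g (lung %d, rng seed %d)\n",
              nrow(object@points), object@radius, object@lungLabel,
              object@rngSeed))
})

setMethod("show", "Partition", function(object) {
  cat(sprintf(
    "Partition: %d subvolumes over %d voxels (r = %g, realization %d, lung %d)\n",
    length(object@sizes), sum(object@sizes), object@radius,
    object@realization, object@lungLabel))
})

setMethod("show", "MetricSpec", function(object) {
  cat("MetricSpec:", specId(object), "\n")
})
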