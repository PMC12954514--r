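#' Construct a VolumeGrid
#'
#' @param values 3D numeric array of voxel intensities.
#' @param spacing voxel spacing in mm (length 3, or a scalar recycled).
#' @return A \linkS4class{VolumeGrid}.
#' @export
VolumeGrid <- function(values, spacing) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(values) <- "double"
  new("VolumeGrid", values = values, spacing = as.numeric(spacing))
}

#' Construct a LungMask
#'
#' @param labels 3D integer array coded 0 = background, 1 = left, 2 = right.
#' @param spacing voxel spacing in mm (length 3, or a scalar recycled).
#' @return A \linkS4class{LungMask}.
#' @export
LungMask <- function(labels, spacing) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(labels) <- "integer"
  new("LungMask", labels = labels, spacing = as.numeric(spacing))
}

#' @rdname accessors
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))
#' @rdname accessors
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("seedPoints", function(x) standardGeneric("seedPoints"))
#' @rdname accessors
#' @export
setGeneric("subvolumeLabels", function(x) standardGeneric("subvolumeLabels"))
#' @rdname accessors
#' @export
setGeneric("subvolumeSizes", function(x) standardGeneric("subvolumeSizes"))

#' Accessors for the imaging and partition classes
#'
#' \code{voxelValues} returns the intensity array of a
#' \linkS4class{VolumeGrid}; \code{maskLabels} the label array of a
#' \linkS4class{LungMask}; \code{voxelSpacing} the mm spacing of either;
#' \code{seedPoints} the n x 3 coordinate matrix of a \linkS4class{SeedSet};
#' \code{subvolumeLabels} and \code{subvolumeSizes} the label array and
#' per-subvolume voxel counts of a \linkS4class{Partition}.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
setMethod("voxelValues", "VolumeGrid", function(x) x@values)
#' @rdname accessors
setMethod("maskLabels", "LungMask", function(x) x@labels)
#' @rdname accessors
setMethod("voxelSpacing", "VolumeGrid", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "LungMask", function(x) x@spacing)
#' @rdname accessors
setMethod("seedPoints", "SeedSet", function(x) x@points)
#' @rdname accessors
setMethod("subvolumeLabels", "Partition", function(x) x@labels)
#' @rdname accessors
setMethod("subvolumeSizes", "Partition", function(x) x@sizes)

#' Construct a MetricSpec
#'
#' Builds one point of the hierarchical metric search space, validating that
#' the supplied fields are exactly those the scenario's processing pathway
#' uses (Voronoi scenarios carry a radius and an intra-subvolume metric;
#' split scenarios carry a left-right operator; \code{P_N} carries its N
#' threshold).
#'
#' @param scenario one of \code{"FULL_LR_TOGETHER"}, \code{"FULL_LR_SPLIT"},
#'   \code{"VORONOI_LR_TOGETHER"}, \code{"VORONOI_LR_SPLIT"}.
#' @param radius Voronoi seed spacing r (isotropic-voxel units), Voronoi
#'   scenarios only.
#' @param intraMetric intra-subvolume statistic, Voronoi scenarios only; one
#'   of MIN, MAX, MEDIAN, MEAN, COV, P25, P75, SKEWNESS, MODE_OVER_MEDIAN.
#' @param interMetric inter-subvolume statistic; one of P_N, COV,
#'   MODE_OVER_MEDIAN, MEDIAN, P25, P75, SKEWNESS.
#' @param nThreshold N in percent (\code{[5, 95]}); required iff
#'   \code{interMetric == "P_N"}.
#' @param lrMetric left-right combination operator, split scenarios only; one
#'   of MIN, MAX, AVG, VOL_WEIGHTED_AVG, PERF_WEIGHTED_AVG, LARGEST_VOL,
#'   SMALLEST_VOL, MOST_PERF, LEAST_PERF.
#' @param valueKind \code{"raw"} or \code{"percentile"}: which map is scored.
#' @return A \linkS4class{MetricSpec}.
#' @examples
#' metricSpec("VORONOI_LR_SPLIT", radius = 20, intraMetric = "MEDIAN",
#'            interMetric = "P_N", nThreshold = 80, lrMetric = "AVG")
#' @export
metricSpec <- function(scenario, radius = NA_real_, intraMetric = NA_character_,
                       interMetric, nThreshold = NA_real_,
                       lrMetric = NA_character_, valueKind = "raw") {
  new("MetricSpec", scenario = scenario, radius = as.numeric(radius),
      intraMetric = as.character(intraMetric),
      interMetric = as.character(interMetric),
      nThreshold = as.numeric(nThreshold),
      lrMetric = as.character(lrMetric), valueKind = valueKind)
}

#' Canonical identifier string of a MetricSpec
#'
#' A parseable encoding \code{scenario|r|intra|inter|N|lr|kind}; absent
#' fields are printed as \code{-}. \code{parseSpecId} inverts it.
#'
#' @param spec a \linkS4class{MetricSpec}.
#' @return \code{specId}: a single string. \code{parseSpecId}: a
#'   \linkS4class{MetricSpec}.
#' @export
specId <- function(spec) {
  chr <- function(x) if (is.na(x)) "-" else x
  paste(spec@scenario, .fmtNum(spec@radius), chr(spec@intraMetric),
        spec@interMetric, .fmtNum(spec@nThreshold), chr(spec@lrMetric),
        spec@valueKind, sep = "|")
}

#' @rdname specId
#' @param id identifier string produced by \code{specId}.
#' @export
parseSpecId <- function(id) {
  f <- strsplit(id, "|", fixed = TRUE)[[1L]]
  if (length(f) != 7L) stop("malformed spec id: ", id)
  num <- function(x) if (x == "-") NA_real_ else as.numeric(x)
  chr <- function(x) if (x == "-") NA_character_ else x
  metricSpec(scenario = f[1L], radius = num(f[2L]), intraMetric = chr(f[3L]),
             interMetric = f[4L], nThreshold = num(f[5L]),
             lrMetric = chr(f[6L]), valueKind = f[7L])
}
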