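# Shared numerical primitives. Every pathway (single-metric calls, the cached
# score-matrix sweep, and the reference globalScore path) routes through the
# same compiled kernels so results are bit-identical regardless of entry
# point.

# All nine intra-subvolume statistics (compiled kernel).
# COV and MODE_OVER_MEDIAN are undefined (NA) when the median is zero.
.intraAll <- function(x) {
  v <- .intraAllCpp(x)
  names(v) <- .INTRA_METRICS
  v
}

#' Intra-subvolume descriptive statistic
#'
#' Summarizes the voxel intensities of one subvolume by a single value.
#' MIN/MAX/MEDIAN/MEAN are standard; P25/P75 are linear-interpolation
#' quantiles; COV is the population standard deviation divided by the median
#' (undefined, \code{NA}, when the median is zero); SKEWNESS is the
#' normalized third central moment (0 for constant input);
#' MODE_OVER_MEDIAN divides the histogram-mode estimate (midpoint of the
#' highest-count bin of 64 equal-width bins over the data range) by the
#' median.
#'
#' @param values nonempty numeric vector of finite voxel intensities.
#' @param metric one of \code{"MIN"}, \code{"MAX"}, \code{"MEDIAN"},
#'   \code{"MEAN"}, \code{"COV"}, \code{"P25"}, \code{"P75"},
#'   \code{"SKEWNESS"}, \code{"MODE_OVER_MEDIAN"}.
#' @return A single number; \code{NA} marks an undefined statistic (a value,
#'   not an error).
#' @examples
#' intraStat(c(1, 2, 3, 4, 5), "MEDIAN") # 3
#' intraStat(c(1, 2, 3, 4, 5), "P25")    # 2
#' @export
intraStat <- function(values, metric) {
  if (length(values) == 0L) stop("empty input to intraStat")
  if (any(!is.finite(values))) stop("non-finite values in intraStat")
  metric <- match.arg(metric, .INTRA_METRICS)
  .intraAll(values)[[metric]]
}

# P_N for a vector of N thresholds (percent): the percentage of total weight
# (lung volume) carried by subvalues at or below N% of the maximum subvalue.
.pnCurve <- function(subvalues, weights, nGrid) {
  mx <- max(subvalues)
  wTot <- sum(weights)
  vapply(nGrid, function(N) {
    100 * sum(weights[subvalues <= (N / 100) * mx]) / wTot
  }, numeric(1))
}

# All inter-subvolume statistics at once: the P_N curve over nGrid plus the
# six unweighted descriptive statistics, named by key ("P_N@<N>" or metric).
# Any NA among the subvalues (an undefined upstream statistic) poisons every
# aggregate.
.interAll <- function(subvalues, weights, nGrid, keys = NULL) {
  if (is.null(keys))
    keys <- c(.pnKeys(nGrid),
              c("COV", "MODE_OVER_MEDIAN", "MEDIAN", "P25", "P75",
                "SKEWNESS"))
  if (anyNA(subvalues)) {
    out <- rep(NA_real_, length(keys))
    names(out) <- keys
    return(out)
  }
  out <- .interAllCpp(subvalues, weights, nGrid)
  names(out) <- keys
  out
}

# Scalar formatting shared by spec ids and P_N keys (element-wise so vectors
# do not get a common width).
.fmtNum <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "-" else format(v, digits = 10, trim = TRUE)
  }, character(1))
}

.pnKeys <- function(nGrid) sprintf("P_N@%s", .fmtNum(nGrid))

#' Inter-subvolume statistic
#'
#' Aggregates per-subvolume summary values across a lung (or the pooled
#' lungs). Non-\code{P_N} metrics apply the \code{\link{intraStat}} formulas
#' unweighted to the subvolume values. \code{P_N} is the percentage of lung
#' volume (subvolume voxel counts as weights) whose subvolume value is at or
#' below N\% of the maximum value across the subvolumes:
#' \deqn{P_N = 100 \cdot \sum_i w_i [v_i \le (N/100) \max_j v_j] / \sum_i w_i.}
#'
#' @param subvalues numeric vector of per-subvolume summary values.
#' @param weights positive weights (subvolume voxel counts), same length.
#' @param metric one of \code{"P_N"}, \code{"COV"}, \code{"MODE_OVER_MEDIAN"},
#'   \code{"MEDIAN"}, \code{"P25"}, \code{"P75"}, \code{"SKEWNESS"}.
#' @param nThreshold N in percent; required iff \code{metric == "P_N"}.
#' @return A single number (percentage for \code{P_N}); \code{NA} marks an
#'   undefined statistic.
#' @examples
#' interStat(c(10, 5, 1), c(1, 1, 1), "P_N", 95) # 66.67: two of three below 9.5
#' @export
interStat <- function(subvalues, weights, metric, nThreshold = NA_real_) {
  if (length(subvalues) == 0L) stop("empty input to interStat")
  if (length(weights) != length(subvalues)) stop("weights length mismatch")
  if (any(weights <= 0)) stop("weights must be positive")
  metric <- match.arg(metric, .INTER_METRICS)
  if (anyNA(subvalues)) return(NA_real_)
  if (metric == "P_N") {
    if (is.na(nThreshold)) stop("P_N requires nThreshold")
    .pnCurve(subvalues, weights, nThreshold)
  } else {
    .intraAll(subvalues)[[metric]]
  }
}

#' Left-right lung combination operator
#'
#' Merges the per-lung summary values into one patient-level score. Because
#' the left and right lungs can differ sharply in health (e.g. unilateral
#' disease), the operators allow differential weighting: plain min/max/mean,
#' averages weighted by lung volume or total perfusion, and selectors that
#' take the value of the larger/smaller lung by volume or the more/less
#' perfused lung. Volume or perfusion ties select the left lung.
#'
#' @param left,right per-lung summary values.
#' @param leftVol,rightVol lung volumes (voxel counts), > 0.
#' @param leftPerf,rightPerf total in-mask perfusion per lung (sums of the
#'   map being scored), >= 0.
#' @param op one of \code{"MIN"}, \code{"MAX"}, \code{"AVG"},
#'   \code{"VOL_WEIGHTED_AVG"}, \code{"PERF_WEIGHTED_AVG"},
#'   \code{"LARGEST_VOL"}, \code{"SMALLEST_VOL"}, \code{"MOST_PERF"},
#'   \code{"LEAST_PERF"}.
#' @return A single number; \code{NA} for \code{PERF_WEIGHTED_AVG} when both
#'   perfusion totals are zero, or when either input is \code{NA}.
#' @export
lrCombine <- function(left, right, leftVol, rightVol, leftPerf, rightPerf,
                      op) {
  op <- match.arg(op, .LR_METRICS)
  if (leftVol <= 0 || rightVol <= 0) stop("lung volumes must be positive")
  if (leftPerf < 0 || rightPerf < 0) stop("perfusion totals must be >= 0")
  if (is.na(left) || is.na(right)) return(NA_real_)
  switch(op,
    MIN = min(left, right),
    MAX = max(left, right),
    AVG = (left + right) / 2,
    VOL_WEIGHTED_AVG = (left * leftVol + right * rightVol) /
      (leftVol + rightVol),
    PERF_WEIGHTED_AVG = if (leftPerf + rightPerf == 0) NA_real_ else
      (left * leftPerf + right * rightPerf) / (leftPerf + rightPerf),
    LARGEST_VOL = if (leftVol >= rightVol) left else right,
    SMALLEST_VOL = if (leftVol <= rightVol) left else right,
    MOST_PERF = if (leftPerf >= rightPerf) left else right,
    LEAST_PERF = if (leftPerf <= rightPerf) left else right)
}

#' Per-lung empirical percentile scaling
#'
#' Independently for each lung, maps every voxel intensity to its empirical
#' percentile: average rank divided by the number of lung voxels, giving
#' values in (0, 1]. Ties share their average rank, so a constant lung maps
#' to (n+1)/(2n) everywhere. Background voxels are left unchanged (they are
#' ignored downstream). Percentile maps are invariant under any strictly
#' increasing transform of the raw intensities.
#'
#' @param grid a \linkS4class{VolumeGrid} of raw intensities.
#' @param mask the paired \linkS4class{LungMask}; both lungs nonempty.
#' @return A \linkS4class{VolumeGrid} of percentiles.
#' @export
toPercentileMap <- function(grid, mask) {
  stopifnot(is(grid, "VolumeGrid"), is(mask, "LungMask"))
  vals <- grid@values
  lab <- mask@labels
  for (lung in c(1L, 2L)) {
    sel <- lab == lung
    n <- sum(sel)
    if (n == 0L) stop("degenerate case: lung ", lung, " is empty")
    vals[sel] <- rank(vals[sel], ties.method = "average") / n
  }
  VolumeGrid(vals, grid@spacing)
}
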