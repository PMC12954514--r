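# 9 x K matrix of intra-subvolume statistics (rows in .INTRA_METRICS order)
# for every subvolume of a partition.
.intraMatrix <- function(vals, partition) {
  sel <- partition@labels > 0L
  m <- .intraGroupsCpp(vals[sel], partition@labels[sel],
                       length(partition@sizes))
  rownames(m) <- .INTRA_METRICS
  m
}

# One intra-subvolume metric evaluated on every subvolume of a partition.
.intraBySubvolume <- function(vals, partition, metric) {
  .intraMatrix(vals, partition)[metric, ]
}

#' Global perfusion score of one case for one MetricSpec
#'
#' Dispatches the hierarchical pathway the scenario prescribes:
#' \describe{
#'   \item{FULL_LR_TOGETHER}{the inter-subvolume statistic applied directly to
#'     the combined lung voxels (each voxel its own subvalue, weight 1).}
#'   \item{FULL_LR_SPLIT}{inter-subvolume statistics per lung, then the
#'     left-right operator.}
#'   \item{VORONOI_LR_TOGETHER}{intra-subvolume statistics per Voronoi
#'     subvolume, subvolumes of both lungs pooled (left first), then the
#'     inter-subvolume statistic.}
#'   \item{VORONOI_LR_SPLIT}{the full three-level path: intra per subvolume,
#'     inter per lung, then the left-right operator.}
#' }
#' For Voronoi scenarios the returned score is the arithmetic mean over the
#' supplied seed realizations (averaging applies to the final global score,
#' not to intermediate levels); an undefined statistic in any realization
#' makes the score undefined (\code{NA}).
#'
#' @param grid a \linkS4class{VolumeGrid} (raw intensities; the percentile
#'   map is derived internally when \code{spec@valueKind == "percentile"}).
#' @param mask the paired \linkS4class{LungMask}.
#' @param spec a \linkS4class{MetricSpec}.
#' @param partitions list of per-realization \code{list(left =, right =)}
#'   \linkS4class{Partition} pairs, as returned by
#'   \code{\link{partitionRealizations}}; required iff the scenario is a
#'   Voronoi one.
#' @return A single number (\code{NA} = undefined).
#' @export
globalScore <- function(grid, mask, spec, partitions = NULL) {
  stopifnot(is(grid, "VolumeGrid"), is(mask, "LungMask"),
            is(spec, "MetricSpec"))
  validObject(spec)
  voronoi <- spec@scenario %in% c("VORONOI_LR_TOGETHER", "VORONOI_LR_SPLIT")
  if (voronoi && is.null(partitions))
    stop("Voronoi scenarios require partitions")
  map <- if (spec@valueKind == "percentile") toPercentileMap(grid, mask)
         else grid
  vals <- map@values
  mlab <- mask@labels
  nl <- sum(mlab == 1L)
  nr <- sum(mlab == 2L)
  vl <- vals[mlab == 1L]
  vr <- vals[mlab == 2L]
  perfL <- sum(vl)
  perfR <- sum(vr)
  inter1 <- function(sv, w) interStat(sv, w, spec@interMetric,
                                      spec@nThreshold)
  switch(spec@scenario,
    FULL_LR_TOGETHER = {
      pooled <- vals[mlab > 0L]
      inter1(pooled, rep(1, length(pooled)))
    },
    FULL_LR_SPLIT = {
      l <- inter1(vl, rep(1, nl))
      r <- inter1(vr, rep(1, nr))
      lrCombine(l, r, nl, nr, perfL, perfR, spec@lrMetric)
    },
    VORONOI_LR_TOGETHER = {
      per <- vapply(partitions, function(p) {
        svl <- .intraBySubvolume(vals, p$left, spec@intraMetric)
        svr <- .intraBySubvolume(vals, p$right, spec@intraMetric)
        inter1(c(svl, svr), c(as.numeric(p$left@sizes),
                              as.numeric(p$right@sizes)))
      }, numeric(1))
      sum(per) / length(per)
    },
    VORONOI_LR_SPLIT = {
      per <- vapply(partitions, function(p) {
        svl <- .intraBySubvolume(vals, p$left, spec@intraMetric)
        svr <- .intraBySubvolume(vals, p$right, spec@intraMetric)
        l <- inter1(svl, as.numeric(p$left@sizes))
        r <- inter1(svr, as.numeric(p$right@sizes))
        lrCombine(l, r, nl, nr, perfL, perfR, spec@lrMetric)
      }, numeric(1))
      sum(per) / length(per)
    })
}
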