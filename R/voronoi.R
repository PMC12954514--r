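#' Poisson-disk seed sampling inside one lung (Bridson's algorithm)
#'
#' Draws a maximal-effort Poisson-disk sample restricted to the voxels of one
#' lung: seeds are uniformly distributed with minimum pairwise spacing
#' \code{radius} (isotropic-voxel units). The first point is drawn uniformly
#' from lung voxels; candidate points are drawn in the spherical annulus
#' [r, 2r) around active points (\code{kAttempts} per active point) and are
#' rejected when their containing voxel lies outside the lung or when they
#' fall within r of an existing seed. Fully deterministic given
#' \code{rngSeed} (a self-contained generator; R's RNG state is untouched).
#'
#' @param mask a \linkS4class{LungMask} on an isotropic grid.
#' @param lungLabel 1 (left) or 2 (right).
#' @param radius minimum seed spacing r, in isotropic-voxel units; >= 1.
#' @param rngSeed integer seed.
#' @param kAttempts candidate attempts per active point (Bridson's canonical
#'   default, 30).
#' @return A \linkS4class{SeedSet}.
#' @export
sampleSeedsBridson <- function(mask, lungLabel, radius, rngSeed,
                               kAttempts = 30L) {
  stopifnot(is(mask, "LungMask"))
  lungLabel <- as.integer(lungLabel)
  if (!(lungLabel %in% c(1L, 2L))) stop("lungLabel must be 1 or 2")
  if (radius < 1) stop("radius must be >= 1 (isotropic-voxel units)")
  if (sum(mask@labels == lungLabel) == 0L)
    stop("degenerate case: lung ", lungLabel, " is empty")
  pts <- .bridsonSampleCpp(as.integer(mask@labels),
                           as.integer(dim(mask@labels)), lungLabel,
                           as.numeric(radius), as.integer(rngSeed),
                           as.integer(kAttempts))
  new("SeedSet", points = pts, radius = as.numeric(radius),
      rngSeed = as.integer(rngSeed), lungLabel = lungLabel)
}

#' Voronoi subvolume assignment of lung voxels to seeds
#'
#' Labels every voxel of the given lung with the 1-based index (in seed
#' order) of its nearest seed by Euclidean distance in isotropic-voxel
#' units; equidistant voxels take the lowest seed index.
#'
#' @param mask a \linkS4class{LungMask}.
#' @param lungLabel 1 or 2; must match the seed set's lung.
#' @param seeds a \linkS4class{SeedSet} for this lung.
#' @param realization realization index recorded on the partition.
#' @return A \linkS4class{Partition}.
#' @export
assignVoronoi <- function(mask, lungLabel, seeds, realization = 1L) {
  stopifnot(is(mask, "LungMask"), is(seeds, "SeedSet"))
  lungLabel <- as.integer(lungLabel)
  if (seeds@lungLabel != lungLabel)
    stop("seed set belongs to lung ", seeds@lungLabel, ", not ", lungLabel)
  lab <- .voronoiAssignCpp(as.integer(mask@labels),
                           as.integer(dim(mask@labels)), lungLabel,
                           seeds@points)
  K <- nrow(seeds@points)
  sizes <- tabulate(lab[lab > 0L], nbins = K)
  if (any(sizes == 0L)) {
    # A seed whose containing voxel was claimed by a nearer neighbour can end
    # up empty; relabel compactly so every subvolume id is nonempty.
    keep <- which(sizes > 0L)
    remap <- integer(K)
    remap[keep] <- seq_along(keep)
    nz <- lab > 0L
    lab[nz] <- remap[lab[nz]]
    sizes <- sizes[keep]
  }
  new("Partition", labels = lab, sizes = as.integer(sizes),
      radius = seeds@radius, realization = as.integer(realization),
      lungLabel = lungLabel)
}

#' Independent Voronoi partition realizations for both lungs
#'
#' Realization k uses \code{rngSeed = baseSeed + k} (and \code{baseSeed + k +
#' 500000} for the right lung so the two lungs draw from distinct streams).
#'
#' @param mask a \linkS4class{LungMask}.
#' @param radius seed spacing r.
#' @param nRealizations number of independent discretizations (default 5).
#' @param baseSeed integer base seed.
#' @param kAttempts Bridson candidate attempts per active point.
#' @return A list of length \code{nRealizations}; each element is a list with
#'   components \code{left} and \code{right} (\linkS4class{Partition}s).
#' @export
partitionRealizations <- function(mask, radius, nRealizations = 5L, baseSeed,
                                  kAttempts = 30L) {
  if (nRealizations < 1L) stop("nRealizations must be >= 1")
  lapply(seq_len(nRealizations), function(k) {
    sl <- sampleSeedsBridson(mask, 1L, radius, baseSeed + k, kAttempts)
    sr <- sampleSeedsBridson(mask, 2L, radius, baseSeed + k + 500000L,
                             kAttempts)
    list(left = assignVoronoi(mask, 1L, sl, k),
         right = assignVoronoi(mask, 2L, sr, k))
  })
}

#' Mean total subvolume count over seed realizations
#'
#' Arithmetic mean, over realizations, of the total number of Voronoi
#' subvolumes (left + right lung).
#'
#' @inheritParams partitionRealizations
#' @return A single number.
#' @export
meanSubvolumeCount <- function(mask, radius, nRealizations = 5L, baseSeed,
                               kAttempts = 30L) {
  parts <- partitionRealizations(mask, radius, nRealizations, baseSeed,
                                 kAttempts)
  mean(vapply(parts, function(p) {
    length(p$left@sizes) + length(p$right@sizes)
  }, numeric(1)))
}

#' Export a partition label map as NIfTI
#'
#' Writes the subvolume labelling as an integer volume for visual inspection
#' of the parcellation.
#'
#' @param partition a \linkS4class{Partition}.
#' @param spacing voxel spacing in mm.
#' @param path output NIfTI path.
#' @return Invisibly, the path.
#' @export
writePartition <- function(partition, spacing, path) {
  lab <- partition@labels
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  attr(lab, "pixdim") <- spacing
  RNifti::writeNifti(lab, path, datatype = "int32")
  invisible(path)
}
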