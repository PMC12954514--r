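#' Read a perfusion volume and its lung mask from NIfTI files
#'
#' Reads a co-registered pair: a 3D scalar perfusion map and an integer lung
#' label mask (0 = background, 1 = left, 2 = right) on the same grid. Shape
#' and spacing must agree; spacing mismatches beyond a small tolerance and
#' unexpected label values are rejected.
#'
#' @param volumePath path to the perfusion NIfTI (.nii / .nii.gz).
#' @param maskPath path to the lung-label NIfTI.
#' @return A list with elements \code{grid} (\linkS4class{VolumeGrid}) and
#'   \code{mask} (\linkS4class{LungMask}).
#' @export
readCase <- function(volumePath, maskPath) {
  if (!file.exists(volumePath)) stop("volume file not found: ", volumePath)
  if (!file.exists(maskPath)) stop("mask file not found: ", maskPath)
  v <- RNifti::readNifti(volumePath)
  m <- RNifti::readNifti(maskPath)
  varr <- array(as.vector(v), dim = dim(v)) # plain array, niftiImage dropped
  marr <- array(as.vector(m), dim = dim(m))
  if (length(dim(varr)) != 3L || length(dim(marr)) != 3L)
    stop("both images must be 3D")
  if (!identical(dim(varr), dim(marr)))
    stop("alignment error: volume shape (", paste(dim(varr), collapse = "x"),
         ") differs from mask shape (", paste(dim(marr), collapse = "x"), ")")
  vs <- RNifti::pixdim(v)[1:3]
  ms <- RNifti::pixdim(m)[1:3]
  if (any(abs(vs - ms) > 1e-5 * pmax(vs, ms)))
    stop("alignment error: volume and mask voxel spacings differ")
  if (!all(marr %in% c(0, 1, 2)))
    stop("mask-coding error: labels outside {0, 1, 2}")
  storage.mode(marr) <- "integer"
  if (sum(marr == 1L) == 0L || sum(marr == 2L) == 0L)
    stop("degenerate case: an empty lung label")
  grid <- VolumeGrid(varr, vs)
  mask <- LungMask(marr, vs)
  inMask <- varr[marr > 0L]
  if (any(!is.finite(inMask)))
    stop("non-finite perfusion values inside the lung mask")
  list(grid = grid, mask = mask)
}

#' Write a perfusion volume and lung mask as NIfTI files
#'
#' Inverse of \code{\link{readCase}}: volumes are stored as double precision
#' so that a write/read round trip is bitwise exact; masks as 16-bit integers.
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @param mask a \linkS4class{LungMask} on the same grid.
#' @param volumePath,maskPath output paths (.nii or .nii.gz).
#' @return Invisibly, the two paths.
#' @export
writeCase <- function(grid, mask, volumePath, maskPath) {
  stopifnot(identical(dim(grid@values), dim(mask@labels)))
  v <- grid@values
  attr(v, "pixdim") <- grid@spacing
  RNifti::writeNifti(v, volumePath, datatype = "double")
  m <- mask@labels
  attr(m, "pixdim") <- mask@spacing
  RNifti::writeNifti(m, maskPath, datatype = "int16")
  invisible(c(volumePath, maskPath))
}

#' Resample a volume/mask pair onto an isotropic grid
#'
#' Intensities are interpolated trilinearly, mask labels by nearest
#' neighbour. Output voxel j has its centre at physical position
#' \code{j * isoMm} along each axis (0-based indices); the output shape is
#' \code{ceiling(extent / isoMm)} where extent is the input shape times its
#' spacing.
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @param mask the paired \linkS4class{LungMask}.
#' @param isoMm target isotropic spacing in mm (default 2.0, between the
#'   in-plane and slice resolutions typical of reconstructed SPECT).
#' @return A list with resampled \code{grid} and \code{mask}.
#' @export
resampleIsotropic <- function(grid, mask, isoMm = 2.0) {
  if (!is.numeric(isoMm) || length(isoMm) != 1L || isoMm <= 0)
    stop("isoMm must be a positive number")
  d <- dim(grid@values)
  if (!identical(d, dim(mask@labels)))
    stop("alignment error: grid and mask shapes differ")
  extent <- d * grid@spacing
  outDims <- as.integer(pmax(1, ceiling(extent / isoMm)))
  vals <- .resampleTrilinearCpp(as.numeric(grid@values), as.integer(d),
                                as.numeric(grid@spacing), isoMm, outDims)
  dim(vals) <- outDims
  labs <- .resampleNearestCpp(as.integer(mask@labels), as.integer(d),
                              as.numeric(mask@spacing), isoMm, outDims)
  dim(labs) <- outDims
  if (sum(labs == 1L) == 0L || sum(labs == 2L) == 0L)
    stop("degenerate case: a lung label vanished at isoMm = ", isoMm)
  list(grid = VolumeGrid(vals, isoMm), mask = LungMask(labs, isoMm))
}

#' Read a pulmonary function test (PFT) table
#'
#' Expects a CSV with header columns \code{case_id, dlco_pct, fev1_pct,
#' fvc_pct, fev1_fvc}. DLCO (% predicted) may be missing (empty cell or NA);
#' all other values are required and must be non-negative. FEV1 and FVC are
#' % predicted; \code{fev1_fvc} is taken exactly as recorded.
#'
#' @param csvPath path to the CSV file.
#' @return A data.frame with one row per case and the five columns above;
#'   missing DLCO is \code{NA}.
#' @export
readPftTable <- function(csvPath) {
  if (!file.exists(csvPath)) stop("PFT table not found: ", csvPath)
  tab <- read.csv(csvPath, stringsAsFactors = FALSE)
  need <- c("case_id", "dlco_pct", "fev1_pct", "fvc_pct", "fev1_fvc")
  missingCols <- setdiff(need, names(tab))
  if (length(missingCols))
    stop("schema error: missing column(s) ", paste(missingCols, collapse = ", "))
  tab <- tab[, need]
  for (col in c("dlco_pct", "fev1_pct", "fvc_pct", "fev1_fvc"))
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  for (col in c("fev1_pct", "fvc_pct", "fev1_fvc"))
    if (any(is.na(tab[[col]])))
      stop("value error: missing ", col, " (only DLCO may be missing)")
  for (col in c("dlco_pct", "fev1_pct", "fvc_pct", "fev1_fvc"))
    if (any(tab[[col]] < 0, na.rm = TRUE))
      stop("value error: negative ", col)
  if (anyDuplicated(tab$case_id)) stop("duplicate case_id in PFT table")
  tab
}
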