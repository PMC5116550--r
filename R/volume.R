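#' Create a VoxelVolume
#'
#' @param data a 3D array (logical, integer or double).
#' @param spacing numeric(3), voxel size in mm along x, y, z.
#' @return A [VoxelVolume-class] object.
#' @examples
#' v <- VoxelVolume(array(0, c(4, 4, 4)), spacing = c(1, 1, 2))
#' dim(v)
#' @export
VoxelVolume <- function(data, spacing = c(1, 1, 1)) {
  new("VoxelVolume", data = data, spacing = as.numeric(spacing))
}

#' Read / write a volume as NIfTI
#'
#' Voxel spacing is taken from (written to) the NIfTI pixdim header fields.
#'
#' @param path file path (\code{.nii} or \code{.nii.gz}).
#' @return `readVolume` returns a [VoxelVolume-class]; `writeVolume` returns
#'   the path invisibly.
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  VoxelVolume(array(as.numeric(img), dim = dim(img)[1:3]), spacing = spacing)
}

#' @rdname readVolume
#' @param vol a [VoxelVolume-class] (logical volumes are written as 0/1).
#' @export
writeVolume <- function(vol, path) {
  dat <- voxelData(vol)
  if (is.logical(dat)) storage.mode(dat) <- "integer"
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- voxelSpacing(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Label connected components of a binary volume
#'
#' Deterministic breadth-first labelling: the component containing the
#' smallest linear index gets label 1.
#'
#' @param mask binary [VoxelVolume-class] or logical array.
#' @param connectivity 26 (default, foreground) or 6.
#' @return integer array of component labels (0 = background).
#' @export
connectedComponents <- function(mask, connectivity = 26) {
  m <- .asMask(mask)
  lab <- .cc_label_cpp(m, dim(m), as.integer(connectivity))
  array(lab, dim(m))
}

#' Euler characteristic of a binary volume
#'
#' Computed under the (26-connected foreground, 6-connected background)
#' convention as objects - tunnels + cavities, by summing generated
#' per-octant contributions of every 2x2x2 voxel window of the cubical
#' complex of the foreground.
#'
#' @param mask binary [VoxelVolume-class] or logical array.
#' @return integer Euler characteristic.
#' @examples
#' cube <- array(TRUE, c(3, 3, 3))
#' eulerCharacteristic(cube)  # 1
#' @export
eulerCharacteristic <- function(mask) {
  m <- .asMask(mask)
  .euler_chi_cpp(m, dim(m))
}

#' Euclidean distance map of a binary volume
#'
#' For every foreground voxel, the exact physical distance (mm) to the
#' nearest background voxel (out-of-grid voxels count as background is NOT
#' assumed here: distances are to in-grid background, matching the notion of
#' distance to the segmented vessel surface).
#'
#' @param mask binary [VoxelVolume-class] or logical array.
#' @param spacing voxel spacing (taken from the volume when omitted).
#' @return numeric array of distances (0 on background).
#' @export
distanceToBackground <- function(mask, spacing = NULL) {
  m <- .asMask(mask)
  spacing <- .spacingOf(mask, spacing)
  ft <- .featureTransform(!m, dim(m), spacing)
  d <- sqrt(ft$dist2)
  d[!m] <- 0
  d[is.na(d)] <- Inf   # no background at all
  array(d, dim(m))
}
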