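#' Voxel predicates used by the thinning algorithm
#'
#' The thinning loop deletes voxels that are simultaneously Border, Line,
#' Euler-invariant and Simple:
#' \itemize{
#'   \item Border: at least one of the 6 face neighbours is background
#'     (out-of-grid counts as background); during thinning the border test is
#'     directional and additionally requires the opposite face neighbour to
#'     be foreground, so each subiteration peels at most a one-voxel shell;
#'   \item Line: more than one of the 26 neighbours is foreground, so
#'     endpoints and isolated voxels are protected;
#'   \item Euler-invariant: removing the voxel leaves the Euler
#'     characteristic (objects - tunnels + cavities) of its 26-neighbourhood
#'     unchanged;
#'   \item Simple: removing the voxel leaves the number of 26-connected
#'     foreground components of its 26-neighbourhood unchanged.
#' }
#'
#' @param voxel integer(3) voxel coordinate (1-based x, y, z) or a single
#'   linear index.
#' @param mask binary [VoxelVolume-class] or logical array; the voxel must be
#'   foreground.
#' @return logical.
#' @export
isBorder <- function(voxel, mask) {
  m <- .asMask(mask)
  co <- .voxelCoord(voxel, dim(m))
  stopifnot(m[co[1], co[2], co[3]])
  dims <- dim(m)
  for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    n <- co + d
    if (any(n < 1) || any(n > dims) || !m[n[1], n[2], n[3]]) return(TRUE)
  }
  FALSE
}

#' @rdname isBorder
#' @export
isLine <- function(voxel, mask) {
  m <- .asMask(mask)
  co <- .voxelCoord(voxel, dim(m))
  stopifnot(m[co[1], co[2], co[3]])
  idx <- .coordToLin(matrix(co, 1), dim(m))
  .nbr26_count_cpp(m, dim(m))[idx] > 1L
}

#' @rdname isBorder
#' @export
isEulerInvariant <- function(voxel, mask) {
  m <- .asMask(mask)
  co <- .voxelCoord(voxel, dim(m))
  stopifnot(m[co[1], co[2], co[3]])
  idx <- .coordToLin(matrix(co, 1), dim(m))
  .delta_chi_cpp(m, dim(m), idx - 1L) == 0L
}

#' @rdname isBorder
#' @export
isSimple <- function(voxel, mask) {
  m <- .asMask(mask)
  co <- .voxelCoord(voxel, dim(m))
  stopifnot(m[co[1], co[2], co[3]])
  idx <- .coordToLin(matrix(co, 1), dim(m))
  .is_simple_cpp(m, dim(m), idx - 1L)
}

.voxelCoord <- function(voxel, dims) {
  if (length(voxel) == 1) voxel <- .linToCoord(as.integer(voxel), dims)[1, ]
  as.integer(voxel)
}

#' Extract the curve skeleton of a binary volume by 3D thinning
#'
#' Iteratively deletes Border-and-Line-and-Euler-invariant-and-Simple voxels
#' until a fixpoint is reached. Each pass sweeps the six face directions as
#' subiterations; within a subiteration, candidates are collected and then
#' deleted sequentially in ascending linear-index (lexicographic x, y, z)
#' order with the Line/Euler/Simple conditions rechecked at deletion time.
#' Sequential rechecked deletion guarantees that the 26-connected component
#' count and the Euler characteristic of the input are preserved; the result
#' is a single-voxel-wide, medially positioned curve skeleton and re-running
#' the operation on its own output is the identity.
#'
#' @param mask binary [VoxelVolume-class] or logical array.
#' @return skeleton of the same carrier type as the input.
#' @examples
#' bar <- array(FALSE, c(9, 5, 5)); bar[, 2:4, 2:4] <- TRUE
#' sum(thin(bar))  # 9-voxel centreline
#' @export
thin <- function(mask) {
  m <- .asMask(mask)
  sk <- .thin_cpp(m, dim(m))
  if (is(mask, "VoxelVolume")) VoxelVolume(array(sk, dim(m)), voxelSpacing(mask))
  else array(sk, dim(m))
}
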