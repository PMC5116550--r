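# Internal index/geometry helpers. Linear indices are 1-based column-major
# over dim = c(nx, ny, nz); voxel (i,j,k) has physical position
# (i-1, j-1, k-1) * spacing (mm).

.linToCoord <- function(idx, dim) {
  idx0 <- idx - 1L
  x <- idx0 %% dim[1]
  y <- (idx0 %/% dim[1]) %% dim[2]
  z <- idx0 %/% (dim[1] * dim[2])
  cbind(x = x + 1L, y = y + 1L, z = z + 1L)
}

.coordToLin <- function(coord, dim) {
  coord <- matrix(as.integer(coord), ncol = 3)
  (coord[, 1] - 1L) + dim[1] * ((coord[, 2] - 1L) + dim[2] * (coord[, 3] - 1L)) + 1L
}

.physical <- function(coord, spacing) {
  sweep(matrix(as.numeric(coord) - 1, ncol = 3), 2, spacing, `*`)
}

.asMask <- function(x) {
  if (is(x, "VoxelVolume")) x <- voxelData(x)
  stopifnot(length(dim(x)) == 3)
  storage.mode(x) <- "logical"
  x
}

.asNumericArray <- function(x) {
  if (is(x, "VoxelVolume")) x <- voxelData(x)
  stopifnot(length(dim(x)) == 3)
  storage.mode(x) <- "double"
  x
}

.spacingOf <- function(x, spacing = NULL) {
  if (!is.null(spacing)) return(as.numeric(spacing))
  if (is(x, "VoxelVolume")) return(voxelSpacing(x))
  rep(1, 3)
}

# Squared physical distance between voxel coordinate rows a (matrix) and a
# single voxel coordinate b, with terms summed in x, y, z order so values are
# bitwise comparable with the C++ feature transform.
.dist2ToVoxel <- function(coords, b, spacing) {
  dx <- (coords[, 1] - b[1]) * spacing[1]
  dy <- (coords[, 2] - b[2]) * spacing[2]
  dz <- (coords[, 3] - b[3]) * spacing[3]
  dx * dx + dy * dy + dz * dz
}

# Nearest seed (1-based linear index) for every voxel; exact Euclidean.
.featureTransform <- function(seeds, dim, spacing) {
  .feature_transform_cpp(as.logical(seeds), as.integer(dim), as.numeric(spacing))
}

# the unique foreground 26-neighbour of a voxel (NA if none or several)
.soleNeighbor <- function(m, co, dims) {
  found <- NA_integer_
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (!dx && !dy && !dz) next
    x <- co[1] + dx; y <- co[2] + dy; z <- co[3] + dz
    if (x < 1 || y < 1 || z < 1 || x > dims[1] || y > dims[2] || z > dims[3]) next
    if (m[x, y, z]) {
      if (!is.na(found)) return(NA_integer_)
      found <- .coordToLin(matrix(c(x, y, z), 1), dims)
    }
  }
  found
}
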