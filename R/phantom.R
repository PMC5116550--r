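#' Specify a synthetic vessel tree
#'
#' Builds and validates a [TreeSpec-class]: a rooted tree of tubular
#' segments (capsules) in physical mm coordinates, together with the voxel
#' grid it will be rasterized into.
#'
#' @param nodes data.frame with columns \code{id, x, y, z} (mm).
#' @param edges data.frame with columns \code{parent, child, radius} (mm).
#' @param spacing numeric(3) voxel size in mm.
#' @param shape integer(3) grid dimensions in voxels.
#' @param seed integer seed recorded for provenance.
#' @return A validated [TreeSpec-class].
#' @export
TreeSpec <- function(nodes, edges, spacing = c(1, 1, 1), shape = c(64, 64, 64),
                     seed = 0L) {
  new("TreeSpec", nodes = as.data.frame(nodes), edges = as.data.frame(edges),
      spacing = as.numeric(spacing), shape = as.integer(shape),
      seed = as.integer(seed))
}

#' Rasterize a vessel tree into a binary volume
#'
#' Each edge is drawn as a capsule (cylinder with hemispherical caps): a
#' voxel is foreground iff its centre lies within the edge radius of the
#' segment between the two node positions. Capsule caps make junctions
#' watertight so no spurious cavities appear at branch points.
#'
#' @param spec a [TreeSpec-class].
#' @return A binary [VoxelVolume-class]; the ground-truth spec is attached as
#'   attribute \code{"spec"}.
#' @examples
#' sp <- TreeSpec(nodes = data.frame(id = 1:2, x = c(5, 25), y = 15, z = 15),
#'                edges = data.frame(parent = 1, child = 2, radius = 2),
#'                shape = c(32, 32, 32))
#' vol <- rasterizeTree(sp)
#' sum(voxelData(vol)) > 0
#' @export
rasterizeTree <- function(spec) {
  stopifnot(is(spec, "TreeSpec"))
  validObject(spec)
  dims <- spec@shape
  sp <- spec@spacing
  mask <- array(FALSE, dims)
  nd <- spec@nodes
  pos <- setNames(split(as.matrix(nd[, c("x", "y", "z")]), seq_len(nrow(nd))), nd$id)
  for (k in seq_len(nrow(spec@edges))) {
    e <- spec@edges[k, ]
    p0 <- pos[[as.character(e$parent)]]
    p1 <- pos[[as.character(e$child)]]
    r <- e$radius
    ext <- (dims - 1) * sp
    if (any(pmin(p0, p1) - r < -1e-9) || any(pmax(p0, p1) + r > ext + 1e-9))
      stop(sprintf("edge %s -> %s (radius %.3g) extends outside the voxel grid; enlarge the shape or shrink the tube",
                   e$parent, e$child, r))
    lo <- pmax((pmin(p0, p1) - r) / sp, 0)
    hi <- pmin((pmax(p0, p1) + r) / sp, dims - 1)
    ix <- seq(floor(lo[1]), ceiling(hi[1])) + 1L
    iy <- seq(floor(lo[2]), ceiling(hi[2])) + 1L
    iz <- seq(floor(lo[3]), ceiling(hi[3])) + 1L
    ix <- ix[ix >= 1 & ix <= dims[1]]
    iy <- iy[iy >= 1 & iy <= dims[2]]
    iz <- iz[iz >= 1 & iz <= dims[3]]
    if (!length(ix) || !length(iy) || !length(iz))
      stop(sprintf("edge %d -> %d rasterizes to no voxels", e$parent, e$child))
    g <- as.matrix(expand.grid(x = ix, y = iy, z = iz))
    P <- .physical(g, sp)
    d <- p1 - p0
    len2 <- sum(d * d)
    if (len2 == 0) {
      t <- 0
      proj <- matrix(p0, nrow(P), 3, byrow = TRUE)
    } else {
      t <- pmin(pmax((sweep(P, 2, p0, `-`) %*% d) / len2, 0), 1)
      proj <- matrix(p0, nrow(P), 3, byrow = TRUE) + t %*% t(d)
    }
    inside <- rowSums((P - proj)^2) <= r * r
    if (!any(inside))
      stop(sprintf("edge %d -> %d is thinner than one voxel after rasterization",
                   e$parent, e$child))
    mask[.coordToLin(g[inside, , drop = FALSE], dims)] <- TRUE
  }
  lab <- .cc_label_cpp(mask, dims, 26L)
  if (max(lab) != 1)
    stop("rasterized tree is not a single 26-connected component")
  out <- VoxelVolume(mask, sp)
  attr(out, "spec") <- spec
  out
}

#' Embed a vessel tree in an ellipsoidal liver phantom
#'
#' The liver mask is the ellipsoid inscribed in the grid; tumours are balls
#' clipped to the liver. Every vessel voxel must fall inside the ellipsoid.
#'
#' @param spec a [TreeSpec-class].
#' @param tumorCenters optional matrix (n x 3) of tumour centres in mm.
#' @param tumorRadii optional numeric(n) tumour radii in mm.
#' @return list with binary [VoxelVolume-class] elements \code{liver},
#'   \code{vessels}, \code{tumors}.
#' @export
makeLiverPhantom <- function(spec, tumorCenters = NULL, tumorRadii = NULL) {
  vessels <- rasterizeTree(spec)
  dims <- spec@shape
  sp <- spec@spacing
  ext <- (dims - 1) * sp
  ctr <- ext / 2
  semi <- ext / 2
  g <- .linToCoord(seq_len(prod(dims)), dims)
  P <- .physical(g, sp)
  q <- ((P[, 1] - ctr[1]) / semi[1])^2 + ((P[, 2] - ctr[2]) / semi[2])^2 +
       ((P[, 3] - ctr[3]) / semi[3])^2
  liver <- array(q <= 1, dims)
  if (any(voxelData(vessels) & !liver))
    stop("vessel voxels fall outside the ellipsoidal liver mask")
  tum <- array(FALSE, dims)
  if (!is.null(tumorCenters) && length(tumorRadii)) {
    tumorCenters <- matrix(tumorCenters, ncol = 3)
    for (k in seq_len(nrow(tumorCenters))) {
      d2 <- rowSums(sweep(P, 2, tumorCenters[k, ], `-`)^2)
      tum[d2 <= tumorRadii[k]^2] <- TRUE
    }
    tum <- tum & liver
  }
  list(liver = VoxelVolume(liver, sp),
       vessels = vessels,
       tumors = VoxelVolume(tum, sp))
}

#' Corrupt a binary vessel mask with cavities and bridges
#'
#' Emulates imperfect vessel segmentation: deterministically (by seed)
#' deletes isolated deep-interior voxels to create internal cavities, and
#' adds thin one-voxel-wide bridges between nearby limbs so that the
#' skeleton graph acquires cycles. The foreground stays a single
#' 26-connected component.
#'
#' @param mask binary [VoxelVolume-class] or logical array.
#' @param cavityRate fraction (in \[0, 0.5)) of eligible deep-interior
#'   voxels to delete.
#' @param bridgeCount number of bridges to add.
#' @param seed integer RNG seed.
#' @param spacing voxel spacing (taken from the volume when omitted).
#' @return corrupted mask, same class as the input data carrier.
#' @export
corruptMask <- function(mask, cavityRate = 0, bridgeCount = 0L, seed = 0L,
                        spacing = NULL) {
  stopifnot(cavityRate >= 0, cavityRate < 0.5)
  m <- .asMask(mask)
  spacing <- .spacingOf(mask, spacing)
  dims <- dim(m)
  if (cavityRate == 0 && bridgeCount == 0) {
    out <- m
  } else {
    out <- m
    rng <- .seededRNG(seed)
    if (cavityRate > 0) {
      # deep interior: all 26 neighbours foreground -> deleting one creates a
      # cavity without touching connectivity; chosen voxels are kept
      # non-adjacent so deletions stay isolated.
      nb <- array(.nbr26_count_cpp(out, dims), dims)
      cand <- which(out & nb == 26L)
      if (length(cand)) {
        nTake <- floor(cavityRate * length(cand))
        ord <- cand[rng$sampleIdx(length(cand))]
        taken <- integer(0)
        takenCoord <- NULL
        for (i in ord) {
          if (length(taken) >= nTake) break
          co <- .linToCoord(i, dims)
          if (is.null(takenCoord) ||
              all(pmax(abs(takenCoord[, 1] - co[1]), abs(takenCoord[, 2] - co[2]),
                       abs(takenCoord[, 3] - co[3])) > 2)) {
            taken <- c(taken, i)
            takenCoord <- rbind(takenCoord, co)
          }
        }
        out[taken] <- FALSE
      }
    }
    if (bridgeCount > 0) {
      added <- 0L
      fgIdx <- which(out)
      co <- .linToCoord(fgIdx, dims)
      tries <- 0L
      maxTries <- 5000L
      while (added < bridgeCount && tries < maxTries) {
        tries <- tries + 1L
        i <- fgIdx[rng$intBelow(length(fgIdx))]
        j <- fgIdx[rng$intBelow(length(fgIdx))]
        a <- .linToCoord(i, dims)[1, ]
        b <- .linToCoord(j, dims)[1, ]
        ch <- max(abs(a - b))
        if (ch < 4 || ch > 20) next
        n <- ch * 2L
        t <- seq(0, 1, length.out = n + 1)
        line <- round(cbind(a[1] + t * (b[1] - a[1]),
                            a[2] + t * (b[2] - a[2]),
                            a[3] + t * (b[3] - a[3])))
        line <- unique(line)
        lin <- .coordToLin(line, dims)
        if (!any(!out[lin])) next       # line stays inside foreground: no new cycle
        out[lin] <- TRUE
        added <- added + 1L
      }
      if (added < bridgeCount)
        stop("bridging impossible within the grid")
    }
    lab <- .cc_label_cpp(out, dims, 26L)
    if (max(lab) > 1) {
      # drop everything but the main component (defensive; cavities are
      # isolated so this should not trigger)
      keep <- which.max(tabulate(lab[lab > 0]))
      out <- array(lab == keep, dims)
    }
  }
  if (is(mask, "VoxelVolume")) VoxelVolume(out, spacing) else out
}

# Small self-contained deterministic RNG (xorshift-like) so corruptMask does
# not disturb the caller's global RNG stream.
.seededRNG <- function(seed) {
  state <- as.integer(seed) %% 2147483647L
  if (state <= 0L) state <- state + 2147483646L
  nextVal <- function() {
    # Park-Miller minimal standard
    state <<- as.integer((as.double(state) * 16807) %% 2147483647)
    state / 2147483647
  }
  list(
    unif = nextVal,
    intBelow = function(n) 1L + as.integer(floor(nextVal() * n)) %% n,
    sampleIdx = function(n) order(vapply(seq_len(n), function(i) nextVal(), 0))
  )
}
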