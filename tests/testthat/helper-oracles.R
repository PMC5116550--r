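# Independent oracles used by the test-suite. These deliberately avoid the
# package's C++ primitives: the Euler characteristic is computed by counting
# cells of the cubical complex with array shifts, connected components by a
# plain R flood fill.

# logical array shifted by (dx, dy, dz), padding with FALSE
.shiftArr <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(FALSE, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

# Euler characteristic chi = V - E + F - C of the union of closed unit
# cubes occupied by foreground voxels
oracleChi <- function(mask) {
  d <- dim(mask) + 2L
  a <- array(FALSE, d)
  a[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- mask
  orShifts <- function(shifts) {
    acc <- array(FALSE, d)
    for (s in shifts) acc <- acc | .shiftArr(a, s[1], s[2], s[3])
    sum(acc)
  }
  # a lattice vertex at the corner (i, j, k) belongs to the complex when any
  # of the 8 voxels meeting there is foreground; edges/faces likewise
  V <- orShifts(list(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1),
                     c(1,1,0), c(1,0,1), c(0,1,1), c(1,1,1)))
  Ex <- orShifts(list(c(0,0,0), c(0,1,0), c(0,0,1), c(0,1,1)))
  Ey <- orShifts(list(c(0,0,0), c(1,0,0), c(0,0,1), c(1,0,1)))
  Ez <- orShifts(list(c(0,0,0), c(1,0,0), c(0,1,0), c(1,1,0)))
  Fx <- orShifts(list(c(0,0,0), c(1,0,0)))
  Fy <- orShifts(list(c(0,0,0), c(0,1,0)))
  Fz <- orShifts(list(c(0,0,0), c(0,0,1)))
  C <- sum(a)
  # vertices belong to 1 voxel-cube each in these shifted counts; faces of
  # the complex are counted per axis-orthogonal orientation
  (V) - (Ex + Ey + Ez) + (Fx + Fy + Fz) - C
}

# number of 26-connected foreground components by R flood fill
oracleComponents <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  comp <- 0L
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  co <- arrayInd(idx, d)
  rownames(co) <- as.character(idx)
  for (start in idx) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cc <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        x <- cc[1] + offs[r, 1]; y <- cc[2] + offs[r, 2]; z <- cc[3] + offs[r, 3]
        if (x < 1 || y < 1 || z < 1 || x > d[1] || y > d[2] || z > d[3]) next
        if (mask[x, y, z] && lab[x, y, z] == 0L) {
          lab[x, y, z] <- comp
          queue <- c(queue, (z - 1L) * d[1] * d[2] + (y - 1L) * d[1] + x)
        }
      }
    }
  }
  comp
}

# brute-force nearest-group labelling in plain R (strict <, so ties keep
# the lower label), for spot-checking classifyVoxels
oracleNearestLabel <- function(queryCoord, groupsVox, spacing) {
  best <- Inf; bestLab <- 0L
  for (k in seq_along(groupsVox)) {
    g <- groupsVox[[k]]
    dx <- (g[, 1] - queryCoord[1]) * spacing[1]
    dy <- (g[, 2] - queryCoord[2]) * spacing[2]
    dz <- (g[, 3] - queryCoord[3]) * spacing[3]
    d2 <- min(dx * dx + dy * dy + dz * dz)
    if (d2 < best) { best <- d2; bestLab <- k }
  }
  bestLab
}

# exhaustive minimum-|Diff| search over outflow subsets, independent of the
# package implementation
oracleBestSubset <- function(rIn, rOutNoncyclic, rCyclic) {
  m <- length(rCyclic)
  if (m == 0) return(integer(0))
  target <- rIn^2 - sum(rOutNoncyclic^2)     # flow ~ cross-sectional area
  bestDiff <- Inf; bestSet <- integer(0); first <- TRUE
  for (bits in 0:(2^m - 1)) {
    sel <- which(bitwAnd(bits, 2^(seq_len(m) - 1)) > 0)
    diff <- abs(target - sum(rCyclic[sel]^2))
    if (first || diff < bestDiff - 1e-12 ||
        (abs(diff - bestDiff) <= 1e-12 && length(sel) < length(bestSet))) {
      bestDiff <- diff; bestSet <- sel; first <- FALSE
    }
  }
  bestSet
}
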