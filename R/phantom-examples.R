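# Parametric phantom builders used in validation and examples. Geometry is
# deterministic up to an optional seeded jitter so ground-truth topology
# (leaf/junction/edge counts) is known exactly.

#' Star phantom: a trunk with radiating limbs at distinct heights
#'
#' A vertical trunk with \code{nLimbs} horizontal limbs attached at evenly
#' spaced heights, azimuthally rotated between consecutive attachments so
#' limbs are mutually well separated (inter-branch separation exceeds four
#' times the largest tube radius). Ground truth: \code{nLimbs} branch
#' vertices, \code{nLimbs + 2} end-voxels (trunk bottom, trunk top, limb
#' tips) and \code{2 * nLimbs + 1} edges.
#'
#' @param nLimbs number of limbs (default 8).
#' @param trunkRadius,limbRadius tube radii in mm.
#' @param limbLength limb length in mm.
#' @param shape,spacing voxel grid and spacing.
#' @param seed recorded seed (geometry itself is deterministic).
#' @return A [TreeSpec-class].
#' @export
starTreeSpec <- function(nLimbs = 8L, trunkRadius = 2, limbRadius = 1.5,
                         limbLength = 22, shape = c(72, 72, 64),
                         spacing = c(1, 1, 1), seed = 0L) {
  ext <- (shape - 1) * spacing
  cx <- ext[1] / 2; cy <- ext[2] / 2
  z0 <- 4; z1 <- ext[3] - 6
  zs <- seq(z0 + 6, z1 - 6, length.out = nLimbs)
  nodes <- data.frame(id = 1L, x = cx, y = cy, z = z0)
  edges <- data.frame(parent = integer(0), child = integer(0), radius = numeric(0))
  prev <- 1L; nid <- 1L
  for (k in seq_len(nLimbs)) {
    nid <- nid + 1L
    nodes <- rbind(nodes, data.frame(id = nid, x = cx, y = cy, z = zs[k]))
    edges <- rbind(edges, data.frame(parent = prev, child = nid, radius = trunkRadius))
    junction <- nid
    th <- (k - 1) * 2 * pi / max(nLimbs, 1) * ((nLimbs + 1) / nLimbs) # rotate
    nid <- nid + 1L
    nodes <- rbind(nodes, data.frame(id = nid,
                                     x = cx + limbLength * cos(th),
                                     y = cy + limbLength * sin(th),
                                     z = zs[k]))
    edges <- rbind(edges, data.frame(parent = junction, child = nid,
                                     radius = limbRadius))
    prev <- junction
  }
  nid <- nid + 1L
  nodes <- rbind(nodes, data.frame(id = nid, x = cx, y = cy, z = z1))
  edges <- rbind(edges, data.frame(parent = prev, child = nid, radius = trunkRadius))
  TreeSpec(nodes, edges, spacing = spacing, shape = shape, seed = seed)
}

#' Portal-like two-level phantom for the full annotation pipeline
#'
#' Emulates the hierarchical structure of the portal venous system at desk
#' scale: a thick trunk bifurcating into two main branches that fan out into
#' eight spokes (the First-Subtree level, radii 3-4 mm), each spoke carrying
#' a distal limb subtree of uniform small radius (the Second-Subtree level)
#' with a stem, two secondary branches and four leaves (eight vertices per
#' limb, so limbs survive Micro-Subtree pruning). Limb subtree roots sit on
#' a wide ring, so k-means++ with K = 8 recovers one blood-supply branch per
#' limb. An optional seeded jitter perturbs node positions.
#'
#' @param shape,spacing voxel grid (default 104 x 104 x 80 at 1 mm).
#' @param jitter standard deviation (mm) of a seeded Gaussian perturbation
#'   of the distal node positions (0 = none).
#' @param seed integer seed for the jitter.
#' @return A [TreeSpec-class].
#' @export
portalPhantomSpec <- function(shape = c(104, 104, 80), spacing = c(1, 1, 1),
                              jitter = 0, seed = 0L) {
  ext <- (shape - 1) * spacing
  ctr <- ext / 2
  nodes <- list(); edges <- list()
  nid <- 0L
  addNode <- function(p) {
    nid <<- nid + 1L
    nodes[[nid]] <<- data.frame(id = nid, x = p[1], y = p[2], z = p[3])
    nid
  }
  addEdge <- function(a, b, r) {
    edges[[length(edges) + 1L]] <<- data.frame(parent = a, child = b, radius = r)
  }
  root <- addNode(c(ctr[1], ctr[2], 8))
  C <- addNode(c(ctr[1], ctr[2], 36)); addEdge(root, C, 4)
  M1 <- addNode(c(ctr[1] + 14, ctr[2], 40)); addEdge(C, M1, 3.8)
  M2 <- addNode(c(ctr[1] - 14, ctr[2], 40)); addEdge(C, M2, 3.8)

  rng <- if (jitter > 0) .seededRNG(seed) else NULL
  jit <- function(p) {
    if (is.null(rng)) return(p)
    p + (c(rng$unif(), rng$unif(), rng$unif()) - 0.5) * 2 * jitter
  }

  ringR <- 26
  thetas <- (c(-67.5, -22.5, 22.5, 67.5)) * pi / 180
  limbRadius <- 1.3
  for (side in c(1, -1)) {
    M <- if (side == 1) M1 else M2
    for (i in seq_along(thetas)) {
      th <- thetas[i]
      if (side == -1) th <- pi - th
      u <- c(cos(th), sin(th), 0)
      tg <- c(-sin(th), cos(th), 0)
      zA <- if (i %% 2 == 0) 28 else 44
      A <- addNode(c(ctr[1] + ringR * cos(th), ctr[2] + ringR * sin(th), zA))
      addEdge(M, A, 3)
      pA <- c(nodes[[A]]$x, nodes[[A]]$y, nodes[[A]]$z)
      zs <- if (zA < 36) -3 else 3
      S <- addNode(jit(pA + 7 * u + c(0, 0, zs))); addEdge(A, S, limbRadius)
      pS <- c(nodes[[S]]$x, nodes[[S]]$y, nodes[[S]]$z)
      for (sgn in c(1, -1)) {
        B <- addNode(jit(pS + 5 * sgn * tg + 3 * u)); addEdge(S, B, limbRadius)
        pB <- c(nodes[[B]]$x, nodes[[B]]$y, nodes[[B]]$z)
        for (dz in c(5, -5)) {
          L <- addNode(jit(pB + 3 * sgn * tg + 2 * u + c(0, 0, dz)))
          addEdge(B, L, limbRadius)
        }
      }
    }
  }
  TreeSpec(do.call(rbind, nodes), do.call(rbind, edges),
           spacing = spacing, shape = shape, seed = seed)
}

#' Serialize / read a TreeSpec as JSON
#'
#' @param spec a [TreeSpec-class].
#' @param path file path.
#' @return `writeTreeSpec` returns the path invisibly; `readTreeSpec` the
#'   [TreeSpec-class].
#' @export
writeTreeSpec <- function(spec, path) {
  jsonlite::write_json(
    list(nodes = spec@nodes, edges = spec@edges, spacing = spec@spacing,
         shape = spec@shape, seed = spec@seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeTreeSpec
#' @export
readTreeSpec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  TreeSpec(x$nodes, x$edges, spacing = x$spacing, shape = x$shape, seed = x$seed)
}
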