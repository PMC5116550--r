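#' VoxelVolume: a 3D image with physical voxel spacing
#'
#' Thin S4 carrier for volumetric data (binary masks, intensity volumes or
#' integer label volumes) together with the per-axis voxel size in
#' millimetres. Arrays are indexed \code{[x, y, z]}; the physical position of
#' voxel \code{(i, j, k)} is \code{(i-1, j-1, k-1) * spacing}.
#'
#' @slot data three-dimensional array (logical, integer or double).
#' @slot spacing numeric(3), voxel size in mm along x, y, z.
#' @export
setClass("VoxelVolume", representation(data = "array", spacing = "numeric"))

setValidity("VoxelVolume", function(object) {
  if (length(dim(object@data)) != 3) return("data must be a 3D array")
  if (length(object@spacing) != 3) return("spacing must have length 3")
  if (!all(is.finite(object@spacing)) || any(object@spacing <= 0))
    return("spacing must be positive and finite")
  TRUE
})

#' TreeSpec: ground-truth specification of a synthetic vessel tree
#'
#' Describes a rooted tree of tubular segments in physical coordinates, used
#' by the phantom generator. Nodes are positions in mm; each edge connects a
#' parent node to a child node and carries the tube radius in mm.
#'
#' @slot nodes data.frame with columns id, x, y, z (mm).
#' @slot edges data.frame with columns parent, child, radius (mm).
#' @slot spacing numeric(3) voxel size (mm).
#' @slot shape integer(3) voxel grid dimensions.
#' @slot seed integer RNG seed recorded for provenance.
#' @export
setClass("TreeSpec", representation(nodes = "data.frame", edges = "data.frame",
                                    spacing = "numeric", shape = "integer",
                                    seed = "integer"))

setValidity("TreeSpec", function(object) {
  nd <- object@nodes; ed <- object@edges
  if (!all(c("id", "x", "y", "z") %in% names(nd))) return("nodes needs id,x,y,z")
  if (!all(c("parent", "child", "radius") %in% names(ed))) return("edges needs parent,child,radius")
  if (anyDuplicated(nd$id)) return("duplicate node ids")
  if (!all(ed$parent %in% nd$id) || !all(ed$child %in% nd$id))
    return("edge endpoints must be node ids")
  if (anyDuplicated(ed$child)) return("a node may have at most one parent")
  roots <- setdiff(nd$id, ed$child)
  if (length(roots) != 1) return("tree must have exactly one root")
  if (nrow(ed) != nrow(nd) - 1) return("edges must form a spanning tree")
  if (any(ed$radius <= 0)) return("radii must be positive")
  if (any(ed$radius < max(object@spacing)))
    return("every radius must cover at least one voxel on each axis")
  ext <- (object@shape - 1) * object@spacing
  pos <- as.matrix(nd[, c("x", "y", "z")])
  if (any(pos < 0) || any(sweep(pos, 2, ext, `>`)))
    return("node coordinates must lie inside the physical grid extent")
  # connectivity: every node reachable from the root
  kids <- split(ed$child, ed$parent)
  seen <- as.character(roots); queue <- seen
  while (length(queue)) {
    nxt <- unlist(kids[queue], use.names = FALSE)
    nxt <- setdiff(as.character(nxt), seen)
    seen <- c(seen, nxt); queue <- nxt
  }
  if (length(seen) != nrow(nd)) return("edges must form a connected tree")
  TRUE
})

#' TopoGraph: measured undirected graph of a vessel skeleton
#'
#' Vertices are topological voxels (end-voxels and resolved branch-voxels);
#' edges are skeleton paths between them with geometric attributes: Length
#' (path length, mm), Distance (straight line between endpoints, mm), Volume
#' (mm^3 of vessel voxels nearest to the edge path), MeanRadius
#' (sqrt(Volume / (pi * Length)), mm) and the raw ratio Volume/(pi*Length)
#' kept for inspection.
#'
#' @slot vertices data.frame: id, vx, vy, vz (voxel), x, y, z (mm), radius
#'   (mm, distance to the nearest non-vessel voxel), kind ("end"/"branch").
#' @slot edges data.frame: id, from, to, length, distance, volume,
#'   meanRadius, meanRadiusRaw, angle (deg, filled after orientation),
#'   cyclic (flagged by BFS orientation), label (vascular system tag).
#' @slot paths list of integer matrices (voxel coordinates along each edge,
#'   including both endpoint vertices).
#' @slot spacing numeric(3) mm.
#' @slot dim integer(3) grid dimensions.
#' @export
setClass("TopoGraph", representation(vertices = "data.frame", edges = "data.frame",
                                     paths = "list", spacing = "numeric",
                                     dim = "integer"))

setValidity("TopoGraph", function(object) {
  v <- object@vertices; e <- object@edges
  need <- c("id", "vx", "vy", "vz", "x", "y", "z", "radius", "kind")
  if (!all(need %in% names(v))) return("vertices missing required columns")
  if (nrow(e) && !all(c(e$from, e$to) %in% v$id)) return("edge endpoints must be vertex ids")
  if (length(object@paths) != nrow(e)) return("one path per edge required")
  if (any(v$radius < 0)) return("vertex radii must be non-negative")
  TRUE
})

#' VesselGraph: an oriented vessel graph with a designated root
#'
#' Produced by breadth-first orientation of a [TopoGraph-class]. Edges are directed
#' from parent to child; edges that close a cycle are flagged in the
#' \code{cyclic} column. May still contain cycles until pruning.
#'
#' @slot root integer vertex id of the main portal vein end-voxel.
#' @export
setClass("VesselGraph", contains = "TopoGraph", representation(root = "integer"))

setValidity("VesselGraph", function(object) {
  if (length(object@root) != 1) return("root must be a single vertex id")
  if (nrow(object@vertices) && !(object@root %in% object@vertices$id))
    return("root must be a vertex id")
  TRUE
})

#' VesselTree: rooted directed acyclic portal-vein tree
#'
#' Final tree after redundant/irrelevant branch removal: acyclic, every
#' non-root vertex has exactly one incoming edge, and the number of edges is
#' the number of vertices minus one.
#'
#' @export
setClass("VesselTree", contains = "VesselGraph")

setValidity("VesselTree", function(object) {
  v <- object@vertices; e <- object@edges
  if (nrow(e) != nrow(v) - 1) return("#edges must equal #vertices - 1")
  inc <- table(factor(e$from, levels = v$id)) # out-degree (unused, kept for clarity)
  indeg <- table(factor(e$to, levels = v$id))
  if (indeg[as.character(object@root)] != 0) return("root must have no incoming edge")
  nonRoot <- setdiff(v$id, object@root)
  if (nrow(v) > 1 && !all(indeg[as.character(nonRoot)] == 1))
    return("every non-root vertex needs exactly one incoming edge")
  TRUE
})

#' RadiusModel: two-component radius mixture and separation threshold
#'
#' Parameters of the two-Gaussian model of branch mean radii: the
#' small-radius (distal) component N(mu2, sigma2) and the large-radius
#' (trunk) component N(mu1, sigma1), the observed radius extremes, and the
#' First/Second-Subtree separation threshold theta = 2*mu2 - Min (clamped to
#' the observed range), or the fallback theta = 0.5 * Max when the fit is
#' degenerate.
#'
#' @export
setClass("RadiusModel", representation(mu1 = "numeric", sigma1 = "numeric",
                                       mu2 = "numeric", sigma2 = "numeric",
                                       rMin = "numeric", rMax = "numeric",
                                       theta = "numeric", fallback = "logical"))

setValidity("RadiusModel", function(object) {
  if (!is.na(object@mu1) && !is.na(object@mu2) && object@mu2 > object@mu1 + 1e-12)
    return("mu2 must not exceed mu1")
  if (object@theta < object@rMin - 1e-9 || object@theta > object@rMax + 1e-9)
    return("theta must lie within [rMin, rMax]")
  TRUE
})

#' BranchDivision: clustered Second-Subtree blood-supply branches
#'
#' Holds the preserved Second Subtrees of a [VesselTree-class] and their k-means++
#' cluster labels; each cluster is one blood-supply branch group, and every
#' skeleton voxel of a subtree inherits its group label.
#'
#' @slot tree the underlying [VesselTree-class].
#' @slot subtrees list; each element has vertex ids, edge ids and the
#'   subtree root vertex id.
#' @slot labels integer cluster label (1..K) per subtree.
#' @slot K integer number of branch groups.
#' @slot centers matrix of cluster centres (mm).
#' @export
setClass("BranchDivision", representation(tree = "VesselTree", subtrees = "list",
                                          labels = "integer", K = "integer",
                                          centers = "matrix"))

setValidity("BranchDivision", function(object) {
  if (length(object@labels) != length(object@subtrees))
    return("one label per subtree required")
  if (length(object@labels) && (min(object@labels) < 1 || max(object@labels) > object@K))
    return("labels must be in 1..K")
  TRUE
})

#' SegmentMap: integer label volume of functional liver segments
#'
#' Labels are 0 outside the liver mask and 1..K inside; every liver voxel is
#' labelled by its nearest blood-supply branch group.
#'
#' @export
setClass("SegmentMap", contains = "VoxelVolume", representation(K = "integer"))

setValidity("SegmentMap", function(object) {
  lab <- object@data
  if (any(lab < 0) || any(lab > object@K)) return("labels must be in 0..K")
  TRUE
})
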