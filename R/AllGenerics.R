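#' @name livertree-accessors
#' @title Accessors for livertree classes
#' @description Accessor generics for the package's S4 containers.
#' @param x an object.
#' @return The corresponding slot content.
NULL

#' @rdname livertree-accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname livertree-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname livertree-accessors
#' @export
setGeneric("vertexTable", function(x) standardGeneric("vertexTable"))

#' @rdname livertree-accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname livertree-accessors
#' @export
setGeneric("edgePaths", function(x) standardGeneric("edgePaths"))

#' @rdname livertree-accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname livertree-accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname livertree-accessors
#' @export
setGeneric("rootVertex", function(x) standardGeneric("rootVertex"))

#' @rdname livertree-accessors
#' @export
setGeneric("segmentLabels", function(x) standardGeneric("segmentLabels"))

#' @rdname livertree-accessors
#' @export
setGeneric("branchLabels", function(x) standardGeneric("branchLabels"))

#' @rdname livertree-accessors
#' @export
setGeneric("radiusThreshold", function(x) standardGeneric("radiusThreshold"))

#' @rdname livertree-accessors
setMethod("voxelData", "VoxelVolume", function(x) x@data)
#' @rdname livertree-accessors
setMethod("voxelSpacing", "VoxelVolume", function(x) x@spacing)
#' @rdname livertree-accessors
setMethod("vertexTable", "TopoGraph", function(x) x@vertices)
#' @rdname livertree-accessors
setMethod("edgeTable", "TopoGraph", function(x) x@edges)
#' @rdname livertree-accessors
setMethod("edgePaths", "TopoGraph", function(x) x@paths)
#' @rdname livertree-accessors
setMethod("nVertices", "TopoGraph", function(x) nrow(x@vertices))
#' @rdname livertree-accessors
setMethod("nEdges", "TopoGraph", function(x) nrow(x@edges))
#' @rdname livertree-accessors
setMethod("rootVertex", "VesselGraph", function(x) x@root)
#' @rdname livertree-accessors
setMethod("segmentLabels", "SegmentMap", function(x) x@data)
#' @rdname livertree-accessors
setMethod("branchLabels", "BranchDivision", function(x) x@labels)
#' @rdname livertree-accessors
setMethod("radiusThreshold", "RadiusModel", function(x) x@theta)

#' @describeIn VoxelVolume-class grid dimensions of the volume.
#' @param x a \code{VoxelVolume}.
#' @export
setMethod("dim", "VoxelVolume", function(x) dim(x@data))

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelVolume %dx%dx%d, spacing %s mm, mode %s\n",
              d[1], d[2], d[3], paste(signif(object@spacing, 4), collapse = "x"),
              storage.mode(object@data)))
  if (is.logical(object@data))
    cat(sprintf("  foreground voxels: %d\n", sum(object@data)))
})

setMethod("show", "TreeSpec", function(object) {
  cat(sprintf("TreeSpec: %d nodes, %d edges, grid %s, spacing %s mm\n",
              nrow(object@nodes), nrow(object@edges),
              paste(object@shape, collapse = "x"),
              paste(signif(object@spacing, 4), collapse = "x")))
  cat(sprintf("  radii: %.2f - %.2f mm\n",
              min(object@edges$radius), max(object@edges$radius)))
})

setMethod("show", "TopoGraph", function(object) {
  cat(sprintf("%s: %d vertices (%d end, %d branch), %d edges\n",
              class(object), nrow(object@vertices),
              sum(object@vertices$kind == "end"),
              sum(object@vertices$kind == "branch"), nrow(object@edges)))
  if (is(object, "VesselGraph"))
    cat(sprintf("  root vertex: %d\n", object@root))
  if (nrow(object@edges))
    cat(sprintf("  mean radius: %.2f - %.2f mm\n",
                min(object@edges$meanRadius), max(object@edges$meanRadius)))
})

setMethod("show", "RadiusModel", function(object) {
  cat(sprintf("RadiusModel: mu2 = %.3f, mu1 = %.3f, theta = %.3f mm%s\n",
              object@mu2, object@mu1, object@theta,
              if (object@fallback) " (fallback 0.5*Max)" else ""))
})

setMethod("show", "BranchDivision", function(object) {
  cat(sprintf("BranchDivision: %d subtrees in %d branch groups\n",
              length(object@subtrees), object@K))
  print(table(labels = object@labels))
})

setMethod("show", "SegmentMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("SegmentMap %dx%dx%d, K = %d, labelled voxels: %d\n",
              d[1], d[2], d[3], object@K, sum(object@data > 0)))
})
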