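#' Full liver functional-region annotation pipeline
#'
#' Runs every stage of the annotation on a liver mask and a vessel input:
#' (optional) vesselness enhancement and vessel segmentation when the vessel
#' input is an intensity image, portal-component selection, topology
#' preserving thinning, measured topological graph construction, root
#' selection and inflow-outflow based conversion to a rooted acyclic vessel
#' tree, radius-threshold subtree hierarchy with Micro-Subtree pruning,
#' k-means++ clustering of subtree roots into \code{K} blood-supply
#' branches, and nearest-branch voxel classification of the liver mask.
#'
#' @param liver binary liver mask ([VoxelVolume-class] or logical array).
#' @param vessels either a binary portal-vessel mask, or a numeric
#'   vessel-enhanced/raw intensity volume (detected automatically: logical
#'   data or exactly two distinct values 0/1 count as a mask).
#' @param tumors optional binary tumour mask within the liver.
#' @param spacing voxel spacing in mm (taken from `liver` when omitted).
#' @param scales Gaussian scales (mm) for multi-scale vesselness when
#'   `vessels` is an intensity volume.
#' @param alpha,beta vesselness sensitivity parameters.
#' @param growThreshold vesselness threshold for region growing; `NULL`
#'   selects it automatically (Otsu).
#' @param theta radius threshold for the subtree split; `NULL` fits the
#'   two-component Gaussian mixture model (see [fitRadiusThreshold()]).
#' @param K number of branch groups (8 for the Couinaud segments).
#' @param seed integer seed controlling all stochastic steps (mixture fit
#'   initialisation and k-means restarts).
#' @param verticesOnly classify against graph vertices only instead of all
#'   skeleton voxels.
#' @param verbose print stage-by-stage progress.
#' @return list with components `vessels` (binary mask used), `skeleton`,
#'   `graph` (the raw [TopoGraph-class]), `tree` ([VesselTree-class]),
#'   `radiusModel`, `theta`, `subtrees`, `division`
#'   ([BranchDivision-class]), `segments` ([SegmentMap-class]), `attributes`
#'   (data.frame), and `lobes` (data.frame or NULL when K != 8).
#' @export
annotateLiver <- function(liver, vessels, tumors = NULL, spacing = NULL,
                          scales = c(1, 2, 3), alpha = 0.3, beta = 0.7,
                          growThreshold = NULL, theta = NULL, K = 8L,
                          seed = 0L, verticesOnly = FALSE, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  spacing <- .spacingOf(liver, spacing)
  L <- .asMask(liver)

  vArr <- if (is(vessels, "VoxelVolume")) voxelData(vessels) else vessels
  isMask <- is.logical(vArr) || all(vArr %in% c(0, 1))
  if (isMask) {
    vMask <- .asMask(vessels)
    say("vessel input: binary mask (%d voxels)", sum(vMask))
  } else {
    say("vessel input: intensity volume; running multi-scale vesselness")
    vness <- multiscaleVesselness(vArr, scales = scales, spacing = spacing,
                                  alpha = alpha, beta = beta)
    vMask <- voxelData(segmentVessels(vness, L, growThreshold = growThreshold,
                                      spacing = spacing))
    say("segmented %d vessel voxels", sum(vMask))
  }
  portal <- selectPortalComponent(vMask)
  say("portal component: %d voxels", sum(portal))

  skel <- thin(portal)
  say("skeleton: %d voxels", sum(skel))

  g <- buildGraph(skel, portal, spacing = spacing)
  say("topological graph: %d vertices, %d edges",
      nrow(g@vertices), nrow(g@edges))

  root <- selectRoot(g)
  og <- orientGraph(g, root)
  og <- removeRedundant(og)
  tree <- removeIrrelevant(og)
  say("vessel tree: root vertex %d, %d edges", tree@root, nrow(tree@edges))

  model <- NULL
  if (is.null(theta)) {
    model <- fitRadiusThreshold(tree@edges$meanRadius, seed = seed)
    theta <- model@theta
    say("radius threshold theta = %.3f mm (%s)", theta,
        if (model@fallback) "fallback 0.5*Max" else "mixture fit")
  } else {
    say("radius threshold theta = %.3f mm (user-supplied)", theta)
  }

  parts <- splitSubtrees(tree, theta)
  kept <- pruneMicro(parts$second)
  say("second subtrees: %d (of %d after Micro-Subtree pruning)",
      length(kept), length(parts$second))

  division <- clusterBranches(tree, kept, K = K, seed = seed)
  say("branch groups: K = %d", division@K)

  seg <- classifyVoxels(L, division, spacing = spacing,
                        verticesOnly = verticesOnly)
  attrs <- segmentAttributes(seg, tumors = tumors, spacing = spacing)
  lobes <- if (division@K == 8L) lobeReport(attrs) else NULL
  say("classified %d liver voxels into %d segments",
      sum(voxelData(seg) > 0), division@K)

  list(vessels = portal, skeleton = skel, graph = g, tree = tree,
       radiusModel = model, theta = theta, subtrees = kept,
       division = division, segments = seg, attributes = attrs,
       lobes = lobes)
}
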