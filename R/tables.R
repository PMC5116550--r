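#' Reference per-segment voxel counts
#'
#' Per-segment voxel counts (SegI..SegVIII, 1 mm^3 voxels) of a
#' representative clinical portal-vein liver annotation, used in examples,
#' report arithmetic and regression tests of [segmentAttributes()] and
#' [lobeReport()].
#'
#' @return named integer vector of eight voxel counts.
#' @examples
#' segmentAttributes(exampleSegmentCounts())
#' @export
exampleSegmentCounts <- function() {
  c(SegI = 53062L, SegII = 78287L, SegIII = 169190L, SegIV = 115116L,
    SegV = 58760L, SegVI = 144737L, SegVII = 152095L, SegVIII = 157323L)
}
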