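Package: livertree
Title: Vessel-Tree-Based Functional Liver Segment Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates the functional (Couinaud) segments of the liver from
    volumetric images of the portal venous system. From a segmented vessel
    volume the package extracts a topology-preserving curve skeleton by 3D
    thinning, builds a measured vascular graph, converts it to a rooted
    acyclic portal-vein tree by inflow-outflow matching, splits the tree
    hierarchically by branch radius, clusters second-level subtrees into
    eight blood-supply branches, and partitions the liver mask into segments
    by nearest-branch classification, producing a quantitative annotation
    report. Includes a synthetic phantom generator with known ground-truth
    topology for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    mclust,
    withr,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
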