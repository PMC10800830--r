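Package: ringseg
Title: Tree-Ring Boundary Segmentation on Stained Wood Microsections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automatic delineation of annual tree-ring boundaries on
    high-resolution RGB images of stained wood microsections, aimed at
    quantitative wood anatomy (QWA). Implements a 2-D UNETR semantic
    segmentation network (vision-transformer encoder with a convolutional
    decoder) trained with the Focal Tversky loss, overlap-tile whole-image
    inference with dihedral test-time augmentation, skeletonization with
    Discrete Skeleton Evolution pruning to recover one-pixel-wide boundary
    paths, and a four-criterion QWA evaluation framework (pixel agreement,
    mean boundary-position spacing, vessel-to-ring mismatch, and expert
    agreement summaries). A synthetic microsection generator with known
    ground truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
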