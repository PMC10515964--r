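Package: devatlas
Title: Desk-Scale Toolkit for Developmental Brain Atlas Construction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building developmental mouse-brain common coordinate
    frameworks at desk scale: light-sheet tile stitching with edge
    maximum-intensity projections, symmetric multi-contrast template
    construction by iterative groupwise registration, landmark- and
    mask-assisted multimodal alignment, reconstruction of sparse 2-D in situ
    hybridization slice series into 3-D template space, hierarchical
    developmental ontology and annotation-volume management, and regional
    voxel quantification. Includes a self-contained multiresolution
    affine-plus-demons registration engine and seeded synthetic phantom
    generators for every fixture the pipeline needs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
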