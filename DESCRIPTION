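Package: fretleaf
Title: Cell-Type-Resolved FRET Biosensor Quantification and Leaf Morphometrics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for ratiometric FRET biosensor imaging of
    abscisic acid in leaves, at cell-type resolution. Segments nuclei from the
    acceptor-excitation channel of confocal z-stacks, computes per-nucleus
    emission ratios (DxAm/DxDm), classifies nuclei into five leaf cell types
    (stomata, pavement, spongy mesophyll, bundle sheath, vascular bundle) from
    nuclear shape and depth, and compares infested versus control conditions
    with FDR-corrected statistics. Companion morphometrics quantify stomatal
    aperture (width/length ratio) and density from impression images, and
    stained area (trypan blue, DAB, chlorosis) from leaf-disk images. A
    synthetic phantom generator with full ground truth makes every stage
    testable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    car,
    emmeans
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: CellBiology, Visualization, Segmentation, Classification
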