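Package: pixphen
Title: Segmentation-Free Cell Phenotyping from Pixel Probability Heatmaps
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Assigns whole-cell phenotypes in multiplex immunofluorescence
    (mIF) images from nuclear labels alone, with no whole-cell segmentation.
    A single-channel two-class U-Net pixel classifier is trained on
    compartment-aware annotations (whole-cell regions for cytoplasmic and
    membranous markers, nuclei only for nuclear markers) so that the
    resulting per-pixel positive-probability heatmaps carry whole-cell
    marker status into the nuclear area. Per-object positivity is called by
    a coverage rule on the heatmap restricted to the nuclear label, and
    marker calls are resolved into phenotypes under an exclusive lineage
    scheme. Includes a synthetic mIF scene simulator with known per-cell
    ground truth, nuclear-label geometry variants for object-size studies,
    a classical mean-intensity expansion baseline, and weighted multiclass
    benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    xml2,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
biocViews: CellBiology, Classification, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
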