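Package: tonodyn
Title: Quantitative Analysis of Plant Vacuole Morphology and Tonoplast Motility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures central-vacuole organization and rapid tonoplast motility
    in plant root rhizodermis cells from single-plane confocal images and
    time-lapse recordings. Implements the vacuolar morphology index (VMI,
    size of the largest vacuolar compartment, natural-log transformed), the
    tonoplast topology index (TTI, membrane crossings per unit length of a
    diagonal cell transect), and a frame-to-first-frame pixel-intensity
    correlation measure of tonoplast motility, together with the supporting
    preprocessing chain (contrast enhancement, 8-bit conversion, rigid-body
    drift registration, rotation, per-cell ROI cropping), kymograph rendering,
    cell-size stratification by pooled median length, and nonparametric
    statistics with Benjamini-Hochberg false discovery rate correction. A
    synthetic tonoplast image and movie generator with known ground truth
    makes every stage testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    car,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
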