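Package: dropseg
Title: Droplet Deposition Detection by Marker-Controlled Watershed Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies spray droplet deposits on reusable
    achromatic-ink carriers imaged under variable ambient illumination.
    Implements an adhesion-aware, modified marker-controlled watershed
    segmentation (shape-degree and area-threshold adhesion tests,
    morphological reconstruction, minima imposition, priority-flood
    watershed), a Beer-Lambert transmittance model linking ambient
    illumination to the ink thickness required for stable imaging, a
    tabular Sarsa agent that adapts an image-contrast parameter to the
    current illumination, deposition metrics (droplet count, coverage,
    coverage density), and a ground-truthed synthetic droplet-scene
    generator so the whole pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    jpeg,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
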