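Package: ardic
Title: Adaptive Reference Digital Image Correlation for Beating Tissue Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Drift-free displacement measurement for time-lapse microscopy of
    spontaneously moving tissue, such as beating cardiomyocyte monolayers.
    Implements multi-pass particle image velocimetry (windowed normalized
    cross-correlation with sub-pixel peak fitting), adaptive reference-frame
    selection driven by a Frobenius-norm threshold with iterative threshold
    refinement, and the downstream spatiotemporal contraction analysis:
    velocity and infinitesimal strain fields, physiology-based contraction
    detection, beats-per-minute estimation, contraction volume, frequency and
    magnitude heat maps, and tree-structured analysis of contracting regions
    (contraction origins, accumulated spatial and spatiotemporal contraction
    maps). Ships a synthetic speckle-video generator with exact displacement
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
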