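Package: bordercell
Title: Quantification of Collective Border-Cell Migration from Fluorescence Time-Lapses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-quantification pipeline for collective border-cell
    migration. Decomposes a migrating cell cluster into subcellular
    F-actin regions (finger-like protrusions, the peripheral supracellular
    actin cable with its broken sections, and inner cell-cell contacts),
    computes group morphometrics (protrusion area fraction, cable
    discontinuity, protrusion count, area, migration speed) and classifies
    groups as tight, loose or balanced. Estimates actin flows by windowed
    zero-normalised cross-correlation (particle image velocimetry),
    interpolates them with masked Gaussian kernels, computes velocity
    divergence by central differences and classifies retrograde versus
    anterograde flow. Ships a synthetic fluorescence time-lapse generator
    with exact ground truth (advected speckle texture, photobleaching,
    noise) so the whole pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
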