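Package: granulytics
Title: Quantitative Analysis of Compartmentalized mRNA Degradation in RNP Granules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying compartmentalized mRNA degradation in the
    Drosophila embryonic germ plasm from single-molecule FISH and live-imaging
    data: diffraction-limited particle detection in 3D confocal stacks,
    internal single-molecule intensity calibration of transcript counts,
    RNP-granule colocalization analysis (pairwise, conditional and
    size-binned), particle tracking with motility statistics, degradation
    time-course and onset inference, and a synthetic microscopy generator
    that provides ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    tiff,
    EBImage,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
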