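Package: crystalscreen
Title: Image-Based Screening of Calcium Oxalate Crystallization Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of brightfield micrographs from calcium
    oxalate (CaOx) crystallization inhibitor screens. Segments individual
    crystals by edge detection and watershed splitting, extracts 15 shape,
    intensity and gray-level co-occurrence texture descriptors per crystal,
    classifies crystals into monohydrate (COM), dihydrate (COD), not-defined
    and background-noise classes with a semi-supervised cubic support vector
    machine, and aggregates class areas into control-normalized dose-response
    series with minimal-inhibitory-concentration calls at a 5 percent rule.
    Includes a seeded, ground-truthed synthetic crystal-scene generator for
    validation without microscopy data, and quantification of crystal-cell
    adhesion and dead-cell readouts from cell assay images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    stats,
    utils,
    grDevices,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
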