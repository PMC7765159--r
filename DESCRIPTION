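Package: dropOx
Title: Spatiotemporal Mapping of Lipid and Protein Oxidation in Emulsion
    Droplets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-droplet analysis of multi-day, three-channel confocal image
    series of oil-in-water emulsions: droplet segmentation (percentile
    normalization, thresholding and distance-transform watershed), LoG spot
    detection with linear-assignment-problem frame linking and gap closing,
    ratiometric quantification of lipid oxidation and interface/aqueous
    protein oxidation, per-droplet Gompertz kinetics, and ANCOVA of
    formulation and droplet-size effects on local oxidation rates. Includes
    a ground-truthed synthetic image generator so every stage is testable
    without real microscopy data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
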