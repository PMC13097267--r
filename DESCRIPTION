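Package: eomhabitat
Title: Water-Fat Habitat Imaging of Extraocular Muscles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Habitat analysis of extraocular muscles from paired water and fat
    MRI signal-intensity volumes, as used to study treatment response in
    thyroid eye disease. Derives cohort-level Otsu thresholds separately for
    the water and fat channels, partitions each muscle mask into four habitat
    subregions (low/low, high/low, low/high, high/high), extracts volumes and
    volume percentages with their longitudinal changes, and evaluates
    candidate response markers with normality-gated group tests, intraclass
    correlation, correlation bands, binary logistic combination and ROC
    analysis with Youden-optimal cutoffs. A synthetic orbital-phantom
    generator with known habitat composition and remodeling dynamics provides
    ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    pROC,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
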