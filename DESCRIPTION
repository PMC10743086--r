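Package: mdrhcs
Title: High-Content Scoring of Multidrug-Resistance Markers in Mixed Tumor Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open pipeline for automated immunofluorescence scoring of
    multidrug-resistance (MDR) markers in mixed cancer/stromal cultures imaged
    in 384-well plates. Segments nuclei from the nuclear channel, assigns
    bounded cytoplasmic cell regions, classifies each cell by epithelial
    (CK8/18) and MDR-marker positivity into four populations, computes
    per-population viability and four-parameter logistic IC50s with censored
    (">cmax") reporting, fold-resistance and selectivity calls, and gates
    marker-induction "increase / no change" calls by Dunnett-adjusted
    significance combined with a biological-relevance threshold. A synthetic
    plate simulator with complete ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    multcomp,
    mvtnorm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
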