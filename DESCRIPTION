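Package: factinquant
Title: Quantitation of Epidermal F-Actin Dynamics During C. elegans Ventral Enclosure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify filamentous-actin organization in time-lapse
    fluorescence movies of Caenorhabditis elegans epidermal morphogenesis:
    leading-edge intensity measurement, ventral-dorsal line-profile peak
    counting and polarization ratios, protrusion lifetime tracking,
    morphogenetic event timing, phenotype-distribution statistics
    (one-way/two-way ANOVA with Tukey and Bonferroni post-tests), and
    western-blot densitometry and subcellular-fractionation arithmetic.
    Includes a seeded synthetic movie generator with full ground truth so the
    whole pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
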