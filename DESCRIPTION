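Package: saquant
Title: Label-Free Semi-Absolute Protein Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes seven label-free relative protein abundance indices
    from peptide-level evidence (PAI, emPAI, SAF, NSAF from spectral counts;
    SUMnorm, TOP3, iBAQ from extracted-ion-chromatogram intensities),
    converts them to absolute amounts (fmol, mol) either by calibration
    against a UPS2-like spiked protein standard with Cook's-distance outlier
    screening, or by the total protein approach, and evaluates the resulting
    techniques (linearity, coefficients of variation, bootstrap absolute
    error, total mass ratio). Includes in-silico tryptic digestion for
    observable-peptide and molecular-weight denominators, and a synthetic
    spike-in data generator with an explicit detection/noise observation
    model so the full workflow runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
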