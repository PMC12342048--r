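Package: degradomics
Title: Protease Cleavage-Site Mapping from Semi-Tryptic Peptide Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Maps protease cleavage sites in a substrate protein from
    label-free quantitative proteomics of paired active-enzyme and
    inactive-control digests. Semi-tryptic peptides enriched in the
    active-enzyme digest are detected by z-score outlier calling on log2
    abundance ratios (with a fixed singleton convention for peptides seen
    in only one condition), candidate P1-P1' bonds are called from their
    non-tryptic termini, and fully tryptic peptides spanning a candidate
    bond provide converse corroborating evidence. Also provides positional
    cleavage-specificity profiling against a background amino-acid
    composition, enzyme-kinetics fits (single-exponential substrate
    depletion for kcat/Km and the Morrison tight-binding equation for
    Ki(app)), and seeded synthetic-data generators for benchmarking the
    whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
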