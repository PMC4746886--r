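Package: ylinkr
Title: Y-Linked Scaffold Detection from Sex-Separated Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate Y-chromosome scaffolds in genome assemblies
    built from separately sequenced male and female DNA libraries. Resolves
    each read's sex of origin from its library name prefix, tallies male and
    female reads per scaffold, and calls scaffolds assembled exclusively from
    male reads as Y-linkage candidates under a binomial false-positive model
    with a minimum-read threshold. Includes contaminant screening and
    evidence-tier triage of candidate genes from tabular homology-search
    results, and a synthetic read-provenance simulator with known chromosomal
    truth for end-to-end calibration and recovery scoring.
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
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
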