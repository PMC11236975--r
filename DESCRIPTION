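Package: adnaudit
Title: Auditing Archiving Practices of Ancient Genomics Sequence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates how completely an ancient-genomics sequencing study has
    been deposited in an INSDC-style archive. A study "bundle" (study, sample,
    run and analysis records plus the referenced FASTQ and SAM/BAM files) is
    scored against a registry of archiving criteria covering raw-read
    archiving, adapter trimming, alignment archiving and hard-filter
    signatures inferred from MAPQ and read-length distributions, read-group
    consistency between BAM headers and archive metadata, sample-metadata
    completeness (geography, dating, radiocarbon lab codes, tissue, voucher),
    and the reporting of negative or low-coverage experiments. Per-study
    verdicts aggregate into per-criterion cohort tables, and a seeded
    generator fabricates synthetic study bundles with planted violations so
    that every detector can be exercised without touching a live archive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
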