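Package: combimark
Title: Composite Genomic Biomarker Discovery from Somatic Variant Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for discovering composite genomic biomarkers of
    drug response from per-patient somatic variant calls. Reads cohort sample
    sheets, annotated SNV/indel VCFs and copy-number segment tables; derives
    per-sample genomic metrics (tumor mutational burden, microsatellite
    instability score, exome amplification/deletion fractions) and trinucleotide
    mutational-signature exposures; screens binary gene-level markers that
    differ between responder groups with a two-sided Fisher exact test; and
    exhaustively searches OR-rule marker combinations (up to a configurable
    panel size) that maximize sensitivity and specificity. Includes seeded
    synthetic-data generators for cohorts, signature-mixture mutation catalogs
    and microsatellite evidence so the full pipeline can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    vcfR,
    pracma,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
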