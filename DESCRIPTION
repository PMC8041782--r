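Package: trapscreen
Title: Diagnostic Metabarcoding of Bulk Insect Trap Catches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting low-abundance pest insects in
    bulk trap samples by multi-locus DNA metabarcoding. Provides curation of
    multi-locus reference databases (length/duplicate, insufficient
    identification, symbiont contaminant and misannotation filters, primer
    region trimming), read quality control with expected-error filtering and
    COI pseudogene screening, naive-Bayes taxonomic classification with
    bootstrap support plus exact-match species assignment, estimation of
    index-switching contamination rates and the derived residual detection
    threshold, multi-locus detection merging against mock-community designs,
    and a synthetic trap-catch simulator that generates reference sets with
    planted database defects, biased mock-community read counts, and index
    switching under combinatorial or unique dual indexing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
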