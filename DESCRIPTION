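Package: mirsites
Title: Distribution of Predicted miRNA Target Sites Across Gene Classes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analyse how predicted microRNA (miRNA) target sites distribute
    across genes. Builds binary gene-by-miRNA interaction matrices from
    TargetScan-style site tables with score-percentile filtering, stratifies
    genes into quartiles and vigintiles by distinct-miRNA counts, computes
    expression variability (coefficient of variation) and promoter-sequence
    noise proxies (GC content and the nucleosome favoring/disfavoring
    dinucleotide ratio), overlays conservation scores, repeat annotations and
    miRNA-gene co-localization, and follows normalized site counts across a
    ladder of species ordered by evolutionary distance. A seeded synthetic-data
    generator with planted class structure supports end-to-end validation
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
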