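Package: pluckseq
Title: Cell-Population Enrichment from Plucked-Hair Versus Skin-Biopsy Bulk RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for contrasting bulk RNA-seq from two
    skin sampling methods (plucked hair and punch biopsy) and projecting the
    differential-abundance results onto a single-cell-derived cell-population
    marker reference. Implements low-expression filtering by reads per million,
    trimmed-mean-of-M-values (TMM) scaling-factor normalization, a conditional
    negative-binomial exact test with common-dispersion estimation and
    Benjamini-Hochberg false-discovery control, cross-species ortholog mapping,
    expressed/significant Venn partitioning, unique-marker extraction, and
    majority-direction enrichment calls per cell population and subpopulation.
    A synthetic-data module simulates mixture-structured counts with
    source-dependent cell-population proportions so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    edgeR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
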