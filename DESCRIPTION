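Package: crescan
Title: Promoter Cis-Regulatory Element Scanning and Representation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts strand-aware upstream promoter windows from a genome and
    its gene annotation, scans them on both strands for degenerate-consensus
    cis-regulatory elements (CREs) written in the IUPAC alphabet, and computes
    the percent-of-genes-carrying-each-CRE statistic per labeled gene set.
    CREs are classified into over-represented (>=75% of promoters),
    moderately over-represented (50-74%) and under-represented (<=49%) tiers,
    gene sets are compared at each tier, and classified CREs are joined to
    their interacting transcription factors and functional categories.
    Includes a classification-only mode for precomputed percent tables and a
    synthetic promoter generator that plants motif instances at known
    per-gene probabilities so every stage is testable against ground truth.
License: MIT + file LICENSE
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
    purrr,
    readr,
    rlang,
    rtracklayer,
    stringr,
    tibble,
    tidyr,
    utils,
    stats,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
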