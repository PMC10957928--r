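Package: ecrescreen
Title: Ensemble Lasso Enhancer Scoring and Candidate Regulatory Element
    Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens chromatin regions for putative enhancers of endothelial
    genes. Implements an ensemble of L1-penalized logistic regressions trained
    on validated enhancers against length-matched shuffled negatives, using
    binary track-overlap and coverage-sum features; averages prediction scores
    over repeated trainings with independently resampled negatives and applies
    a 0.5 decision threshold. Also implements the surrounding discovery stage:
    consensus peaks across replicates, blacklist filtering, two-caller
    consensus of differentially accessible regions, nearest-TSS gene
    annotation, intersection with marker-gene lists, candidate reports and
    motif co-presence summaries. Includes a synthetic-data generator with
    known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    glmnet,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
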