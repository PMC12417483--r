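Package: complaintlens
Title: Patient-Complaint Text Mining with Adaptive Density Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for mining free-text patient complaints in hospital
    service-quality work. Cleans and tokenizes complaint tables (including
    mechanical compression of machine-repeated text and stop-word filtering),
    scores documents against a word-score sentiment lexicon with a sign-based
    polarity rule, vectorizes the corpus with TF-IDF, clusters complaints with
    DBSCAN under an adaptive parameter search that derives epsilon candidates
    from K-average nearest-neighbor distances and the density threshold from
    the expected neighborhood size, extracts per-cluster keywords, and computes
    service-quality indicators (overall satisfaction, compensation and petition
    rates, 2x2 chi-square group comparisons). Ships deterministic synthetic-data
    generators so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
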