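Package: comorbnet
Title: Co-Occurrence Network Analysis of Diagnoses and Comorbidities in
    Hospital Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing co-occurrence patterns of diagnoses and
    comorbidities in electronic medical record (EMR) cohorts, developed
    around a coronary artery disease (CAD) case study. Provides term
    normalisation via mapping tables, detection rates with Wilson
    confidence intervals, sex-specific odds ratios with the
    Haldane-Anscombe continuity correction, age/sex/year stratified
    top-k tables, weighted monopartite and bipartite co-occurrence
    networks, network metrics including weighted modularity (seeded
    Louvain optimisation) and the two-level map-equation description
    length, an edge-weight-threshold sensitivity sweep, a calibrated
    synthetic cohort simulator with a shared-frailty co-occurrence
    structure, and an end-to-end pipeline that writes reproducible
    tabular and graph artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
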