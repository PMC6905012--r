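Package: macna
Title: Multi-Analyte Correlation Network Analysis for Case-Control Biomarker Panels
Version: 0.1.0
Authors@R: person("macna", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds hard-thresholded Pearson correlation networks over
    multiple biomarker variable groups (anthropometric, metabolic, immune
    cell abundance, serum cytokine, gut microbiome), computes node degree,
    normalized betweenness centrality, per-group network density and
    betweenness-based hubs, collapses cross-group connectivity to a
    group-level meta-network, and compares case and control cohort
    networks. Includes unpaired t-tests (Welch or pooled, from raw data or
    published summary statistics) and a seeded synthetic-cohort generator
    with planted correlation structure for validation of the full
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
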