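Package: carepath
Title: Multidimensional State Sequence Analysis of Pediatric Diabetes Care Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for clustering longitudinal care pathways from health-claims
    tables. Encodes per-patient healthcare events into multichannel state
    sequences (quarterly outpatient contact, quarterly glycemic diagnostics,
    annual complication screening), computes longest-common-subsequence
    dissimilarities pooled across dimensions after per-matrix min-max
    normalization, partitions patients around medoids with quality-index model
    selection (average silhouette width, point-biserial correlation, Hubert's C),
    and profiles the resulting clusters against socioeconomic covariates and
    hospitalization outcomes. Includes a synthetic claims-data generator with a
    planted two-archetype mixture so the full pipeline is testable without
    access to restricted insurer data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
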