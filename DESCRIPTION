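Package: mmtraj
Title: Multimorbidity Clusters and Disease Trajectories from Hospital Registry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-scale analysis of disease trajectories from hospital
    stay records. Patient histories of ICD-10 diagnoses are encoded as
    cumulative binary vectors over WHO diagnosis blocks, partitioned into
    interpretable multimorbidity clusters by monothetic divisive clustering,
    and linked by a sex- and age-stratified multilayer network of yearly
    cluster transition rates. On top of the network the package derives
    reduced disease trajectories and their statistics, mortality regions,
    high-risk entry clusters, stratified relative risks with confidence
    intervals, Fisher-exact comorbidity comparisons, and a generative Markov
    trajectory simulator with single-disease benchmark models. A synthetic
    hospital-registry generator with known ground-truth dynamics makes the
    whole pipeline testable without access to confidential registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Matrix,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
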