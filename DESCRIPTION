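Package: mmnet
Title: Multimorbidity Network Analysis for Type 2 Diabetes Comorbidities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses sex- and age-specific multimorbidity networks
    from patient-level ICD-10 diagnosis records of a type 2 diabetes cohort.
    Edges are weighted by the Salton cosine index and calibrated against a
    phi-coefficient significance screen so that only positively correlated
    disease pairs are retained. Provides network metrics (degree, weighted
    degree, density, closeness and harmonic centrality), identification of
    hub (PageRank), root (eigenvector centrality within Louvain communities),
    burst (degree growth across age strata) and core diseases, cumulative
    yearly networks for temporal degree trends, and perturbation analyses of
    node removal and random edge deletion. Includes a synthetic electronic
    medical record generator with planted co-occurrence clusters and hubs so
    the full pipeline is testable without access to restricted hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils,
    xml2
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
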