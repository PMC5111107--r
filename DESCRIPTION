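Package: crcbench
Title: Cross-Validation Benchmark for Colon Cancer Molecular Subtype
    Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A workbench for cross-validating gene-expression-based colon
    cancer subtype classifiers on a common cohort. Harmonizes log2
    expression matrices (TSV and GEO series-matrix dialects), collapses
    probes to genes, and removes redundant samples; executes
    formula-specified risk classifiers (linear scores, product-ratio
    scores, delta-Ct transforms, per-gene tallies, group-mean comparisons)
    from declarative signature definitions; retrains centroid-style
    engines (nearest centroid, nearest shrunken centroid, compound
    covariate predictor, meta-gene linear discriminant, KNN, linear
    maximum-margin); quantifies classifier agreement with Cramer's V,
    signature gene overlap, and a gene-score ranking; benchmarks
    classifiers against relapse-free survival with best-versus-worst
    cohort Cox models, Kaplan-Meier/log-rank analyses, univariate gene
    screens and multivariate adjustment; assigns cell lines to subtypes by
    replicate-array consensus; and simulates cohorts with planted subtype
    structure and subtype-dependent exponential survival so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    class
Config/testthat/edition: 3
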