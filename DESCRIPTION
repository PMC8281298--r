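Package: methyltraj
Title: DNA Methylation Trajectory Analysis for Differentiation Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for array-style DNA methylation time courses
    of stem-cell differentiation: detection p-value and intensity quality
    control, dasen-style normalization, epigenetic-clock age prediction with
    stage-wise ANOVA/Tukey comparisons, pseudotime inference by principal
    curves through k-means cluster centers, a vectorized penalized-spline
    scan for loci whose methylation changes progressively along pseudotime
    with Bonferroni selection and shape-module clustering, probe-level and
    probe-bias-adjusted (Wallenius) gene-set enrichment, and directed
    gene-gene network topology analysis of the strongly connected component.
    Includes a synthetic-data generator emulating a 4-stage by 4-replicate
    EPIC-array differentiation experiment so every stage of the pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    igraph,
    limma,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    yaml,
    optparse
Config/testthat/edition: 3
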