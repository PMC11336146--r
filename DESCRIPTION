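Package: SigScan
Title: Prognostic Gene Signatures by Directional Cox Screening and
    Optimal-Cutoff Survival Scanning
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and validates prognostic gene-expression signatures for
    relapse-free survival from multi-dataset microarray cohorts. Each gene is
    screened with a univariate Cox proportional-hazards model and weighted +1
    or -1 by the direction of its hazard ratio; the signature score is the
    average weighted expression over signature genes. Samples are
    dichotomized by scanning every observed score between the lower and upper
    quartiles, with Benjamini-Hochberg false-discovery-rate correction across
    scanned cutoffs, Kaplan-Meier curves and log-rank tests at the selected
    cutoff, dataset-wise replication with a sufficiency filter, and paired
    bivariate Cox models against clinical covariates. A synthetic cohort
    generator with known per-gene effects, dataset batch shifts and
    calibrated censoring supports end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    survival,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite,
    readxl
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Survival, GeneExpression, Microarray, Software
RoxygenNote: 7.3.3
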