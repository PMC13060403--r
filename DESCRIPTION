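Package: latentstrat
Title: Deep-Latent Stratification of Registry-Based Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies registry-style case-control cohorts with a beta-variational
    autoencoder over mixed clinical features (binary, categorical, count, continuous,
    with missingness), followed by consensus k-means subtyping with clusterability
    (Hopkins) and Monte-Carlo cluster-number significance testing, perturbation-based
    feature importance, and mapping of common-variant (polygenic score) and
    rare-variant (CADD-filtered gene-set burden) genetic signal onto clusters through
    a one-vs-rest regression enrichment framework with overdispersion switching and
    multiplicity control. Includes a synthetic-cohort generator with planted latent
    cluster structure so the full pipeline is testable without restricted registry
    or exome data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    cluster,
    vcfR,
    rlang
Suggests:
    testthat (>= 3.0.0),
    mclust,
    clue,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
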