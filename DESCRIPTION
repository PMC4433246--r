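Package: microcore
Title: Core Microbiota, Diversity and Indicator Taxon Analysis for
    Paired-Marker Amplicon Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing gut-microbiota OTU count tables obtained
    from two independent 16S rRNA amplicons of the same specimens. Implements
    occurrence-based OTU retention filters with a taxon-exclusion rule,
    rarefaction and rank aggregation, alpha diversity (Chao1, Shannon,
    Faith's phylogenetic diversity) with rarefaction averaging, beta
    diversity (binary Jaccard, unweighted and weighted UniFrac, Manhattan on
    arcsine-transformed relative abundances), principal coordinates analysis,
    Procrustes comparison of ordinations with Monte Carlo significance,
    distance-based permutational MANOVA, a multi-criterion core-microbiota
    computation with a permutational relative-core-length test, and indicator
    value (IndVal) analysis with a cross-marker concordance filter. A
    synthetic-community generator emulating a multi-species host survey with
    planted core structure provides ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    biomformat,
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
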