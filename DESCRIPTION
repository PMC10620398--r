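Package: mcseedr
Title: Methylation-Content-Sensitive Enzyme ddRAD Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for reduced-representation DNA methylation
    profiling based on methylation-content-sensitive double-digest locus
    readout (MCSeEd-style assays). Provides in-silico restriction digestion
    and enzyme ranking, locus-by-sample count matrix assembly with library
    standardization and coverage filtering, relative methylation estimation
    with PCA quality control, logistic-regression differential methylation
    position (DMP) testing with FDR control, iterative window-width-optimized
    differentially methylated region (DMR) calling, strand-aware gene and
    regulatory-region assignment, early/mid-response gene classification,
    hypergeometric term enrichment with dual-correction consensus, and
    2^-ddCt qPCR agreement analysis. Includes a synthetic-data generator
    that emulates the statistical structure of the assay so every stage is
    testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
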