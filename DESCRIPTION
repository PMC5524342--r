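Package: doestrare
Title: Rare-Variant Association Testing via Mutation Position Densities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene-based case/control association tests for rare genetic
    variants. Implements the DoEstRare test, which compares kernel density
    estimates of rare-mutation positions between cases and controls, each
    scaled by a weighted mean allele frequency, with significance assessed
    by standard or adaptive phenotype permutation. Includes CAST-style and
    weighted-sum burden comparators, a synthetic haplotype-pool simulator
    with clustered and non-clustered disease-risk-variant scenarios under a
    logistic disease model, replicate runners for type I error and power
    estimation, and VCF/BED/TSV ingestion and serialization.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
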