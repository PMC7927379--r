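Package: breedPLS
Title: One-vs-Rest Partial Least Squares Scans for Breed-Specific Selection Signatures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies SNPs that distinguish each population (breed) of a
    multi-breed genotype panel from all others using one-vs-rest partial
    least squares (PLS) regression on SNP dosages, with per-locus
    significance calls, gene mapping, hypergeometric term enrichment and
    interaction-network module scoring. Includes a Balding-Nichols
    multi-population genotype simulator with planted breed-specific loci
    for benchmarking, VCF input/output with minor-allele-frequency
    filtering and imputation, genetic-relationship-matrix PCA and classical
    principal coordinates analysis, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, PopulationGenetics, DimensionReduction,
    GeneSetEnrichment, Network
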