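Package: wrassepop
Title: Population Genomics of SNP Panels: Differentiation, Assignment and
    Diagnostic Marker Selection
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for SNP-based population genomics of non-model species:
    k-mer-spectrum mixture modelling of genome size and heterozygosity by
    expectation-maximization, site and locus filtering (quality, minor allele
    frequency, Hardy-Weinberg with false-discovery-rate correction, physical
    thinning), diversity and Weir-Cockerham FST statistics with bootstrap
    confidence intervals, linkage-disequilibrium surveys, UPGMA individual
    distance trees with bootstrap support, discriminant analysis of principal
    components (DAPC) with BIC-based cluster number and alpha-optimized PC
    retention, Monte-Carlo cross-validated assignment, PCA/Mahalanobis outlier
    scans with Storey q-values, and selection and validation of diagnostic SNP
    panels. Includes Balding-Nichols genotype and parametric k-mer spectrum
    simulators so every stage can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    ape,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
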