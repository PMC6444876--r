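Package: qtlgene
Title: Conditional QTL Detection and Candidate-Gene Prioritization for
    Quantitative Traits
Version: 0.1.0
Authors@R: person(given = "Package", family = "Author",
    email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-GWAS inference chain for continuous traits measured on
    genotyped populations, built around dairy-cattle fertility mapping:
    quality-control filtering of imputed dosages (minor allele frequency
    and Hardy-Weinberg tests), single-marker association scans by ordinary
    least squares or a mixed linear model with a genomic relationship
    matrix, iterative conditional lead-SNP discovery with solo-SNP
    filtering and QTL-interval delineation, linkage-disequilibrium r2
    linking of significant variants to lead SNPs, gene-based association
    by principal-components regression, and integration of Gene Ontology,
    KEGG, mouse-phenotype and differential-expression evidence into a
    prioritized candidate-gene table. Includes a genotype/phenotype
    simulator with distance-decaying linkage disequilibrium and planted
    QTL so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
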