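Package: relictpop
Title: Population-Genomic Diversity Analysis for Relict Crop-Wild Cohorts
Version: 0.1.0
Authors@R: person("relictpop", "maintainers", email = "relictpop@example.org",
    role = c("aut", "cre"))
Description: An all-sites-VCF population genetics toolkit built around the
    analysis of small relict populations of crop wild relatives (allopolyploid
    cotton in particular). Provides missing-data-aware windowed nucleotide
    diversity (pi), between-group divergence (dxy) and Weir-Cockerham Fst with
    invariant-site denominators; per-individual heterozygosity and inbreeding
    coefficients; Yang-style genotype relatedness; linkage-disequilibrium decay
    with subsample replication and windowed r2 pruning; PCA on standardized
    genotypes, identity-by-state distances and neighbor-joining trees with
    outgroup rooting; folded site frequency spectra and windowed Tajima's D; a
    reference-panel novel-allele classifier with UpSet-style overlap
    decomposition; and a forward Wright-Fisher simulator (two-subgenome layout,
    serial bottlenecks, migration, partial selfing) that generates all-sites
    cohorts with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    methods
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
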