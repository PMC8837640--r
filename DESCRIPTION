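Package: popdiv
Title: Variant Filtering, Annotation, Nucleotide Diversity and Linkage
    Disequilibrium Decay for Resequencing Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for population-genetic analysis of diploid resequencing
    variant panels such as crop cultivar collections. Reads VCF genotype
    data into an annotated genotype matrix, applies the two standard SNP
    subset filters (biallelic/polymorphic and missingness, heterozygosity,
    minor-allele-frequency thresholds), classifies variants by genomic
    region and coding effect (sequence-ontology terms up to bidirectional
    gene fusion), computes windowed nucleotide diversity (pi) and
    polymorphic information content (PIC) with sub-population reporting by
    year-of-release bins, and estimates linkage-disequilibrium decay curves
    with the r-squared half-decay distance. A seeded simulator generates
    genotype panels, LD haplotypes and an annotated toy genome with a
    machine-readable truth ledger so that every stage is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'popdiv-package.R'
    'AllGenerics.R'
    'GeneModel-class.R'
    'GenotypeMatrix-class.R'
    'annotation.R'
    'site-filters.R'
    'diversity.R'
    'io-annotation.R'
    'io-vcf.R'
    'ld.R'
    'simulate.R'
    'toy-genome.R'
    'pipeline.R'
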