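Package: VariantCatalog
Title: High-Confidence Biallelic SNP Catalogs from Heterogeneous
    Whole-Genome Call Sets
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds and characterizes high-confidence biallelic SNP
    catalogs by intersecting heterogeneous whole-genome variant call
    sets (short-read individual, short-read pooled, and long-read
    data). Provides per-dataset genotype- and site-level quality
    filters, allele-aware intersection with chromosome-class-specific
    merge rules, read-depth-based group allele frequencies and call
    rates for individuals and DNA pools, genome-window marker density
    and spacing statistics, per-window candidate budgeting for SNP
    array design, and population-structure summaries (PCA and
    hierarchical clustering of genotype dosages). A synthetic-data
    module simulates the three call sets with known truth under a
    Balding-Nichols divergence model so that every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    vcfR,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'GenomeLayout-class.R'
    'VariantCatalog-package.R'
    'VariantSet-class.R'
    'chip.R'
    'density.R'
    'filters.R'
    'group-stats.R'
    'merge.R'
    'mnp.R'
    'pipeline.R'
    'simulate.R'
    'structure.R'
    'vcf-io.R'
    'windows.R'
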