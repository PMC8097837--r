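Package: cagpipe
Title: Gene-Level Metagenomics with Co-Abundant Gene Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene-level analysis of shotgun metagenomes. Resolves
    multi-mapping reads against a protein gene catalog with an
    expectation-maximization procedure that favours even sequencing
    coverage, computes length-normalized gene depth and relative
    abundance, groups genes into co-abundant gene groups (CAGs) by
    sharded average-linkage clustering under the cosine distance with a
    nearest-neighbour pre-filter, fits per-CAG beta-binomial regressions
    of read counts on specimen covariates with Benjamini-Hochberg FDR
    control, aggregates CAG-level coefficients to taxon or function
    level with an errors-in-response random-effects model, and detects
    contiguous genomic islands of outcome-associated genes on reference
    genomes. Includes a seeded synthetic-data generator providing ground
    truth for every stage and an HDF5 results store.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    metafor,
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'abundance.R'
    'aggregate.R'
    'betabinom.R'
    'cagpipe-package.R'
    'clustering.R'
    'io.R'
    'islands.R'
    'pipeline.R'
    'store.R'
    'synthgen.R'
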