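Package: GenesetCompare
Title: Structural Comparison of Gene Annotation Sets and Their Impact on
    Variant and Expression Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing two transcript-level gene annotation sets
    ("genesets", e.g. a GENCODE-like and a RefSeq-like annotation).
    Derives standard annotation subsets (comprehensive, basic, curated
    accessions) via declarative filter rules, quantifies transcripts,
    translations and exons shared between or unique to each geneset using
    intron-chain and CDS-chain equivalence keys, classifies variant
    functional annotation as concordant, discordant or unique under each
    geneset with a built-in minimal consequence caller, and summarises
    exon and intron expression from per-base coverage tracks.  A fully
    deterministic synthetic-data generator produces paired genesets,
    variants, coverage tracks and a reference sequence with complete
    ground-truth bookkeeping, so every pipeline stage can be exercised
    and validated without external genome-scale resources.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
biocViews: Annotation, Transcriptomics, VariantAnnotation, Software
RoxygenNote: 7.3.3
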