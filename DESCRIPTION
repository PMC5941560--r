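Package: tetramerge
Title: Multi-Caller Variant Call Harmonization for Tetraploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes structural and small variant calls from a suite of
    variant callers (small-variant, split-read, read-pair, and read-depth
    based) into a unified, genome-wide mutation catalog for a tetraploid
    cell line genome. Implements per-caller quality filtering, assembly-gap
    masking, reciprocal- and one-way-overlap interval algebra, hierarchical
    cross-caller merging with a dedicated homozygous-deletion pipeline,
    binned read-depth to integer copy-number conversion, matching against
    dbSNP-, ClinVar-, DGV- and dbVar-style variant databases, and
    hypergeometric gene-set enrichment of damaged genes. Ships a synthetic
    tetraploid call-set generator with a ground-truth manifest so the whole
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
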