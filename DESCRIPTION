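Package: snpground
Title: Normalization of SNP Mentions in Biomedical Text to Variant Database Records
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Recognizes protein-level (PSM), nucleotide-level (NSM) and
    rs-identifier mentions of single nucleotide polymorphisms in plain
    biomedical text, converts variant positions among four historical human
    mutation nomenclature conventions (cap-site transcript numbering,
    genomic numbering, the IVS convention and HGVS-style coding-DNA
    numbering) over explicit gene models, and grounds mentions to
    dbSNP-style records. The matching algorithm recovers systematic
    discrepancies between text and database records, including
    initiator-methionine cleavage offsets, mature-protein feature offsets,
    opposite-strand allele storage, flipped wild-type/mutated
    directionality, duplicate co-located records and digit-permuted rs
    identifiers. Includes a worked MECP2-like gene-model fixture, fixture
    stores for the documented error classes, a seeded synthetic corpus
    generator for end-to-end evaluation, and precision/recall scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
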