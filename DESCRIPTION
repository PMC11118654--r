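Package: sigkit
Title: Mutational Signature Extraction, Assignment and Exposure Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Catalog-level analysis of somatic mutational processes:
    classification of single base substitutions, doublet substitutions,
    small insertions and deletions, copy-number segments and structural
    variants into COSMIC-style context categories; de novo signature
    extraction by replicated nonnegative matrix factorization with
    hypermutator normalization and stability-based rank selection; sparse
    signature assignment by forward-stagewise nonnegative least squares
    with configurable cohort rescue rules; probabilistic attribution of
    individual mutations to signatures; signature-injection power
    simulation; and regression-based association of exposures such as
    fine particulate air pollution and passive smoking with mutation
    burden, signature activities and telomere length. A seeded
    synthetic-cohort generator provides end-to-end validation without
    access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    cluster,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
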