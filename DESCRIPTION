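Package: isotrx
Title: Long-Read Isoform Classification and Tumour-Specific Transcript Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Structural classification of full-length long-read transcript
    models against a reference annotation (full-splice match, incomplete-splice
    match, novel-in-catalogue, novel-not-in-catalogue, antisense, intergenic),
    an artifact-filter cascade (short-read splice-junction support, genomic
    intrapriming poly(A) tracts, cross-sample non-redundant merging, replicate
    support), differential transcript and gene expression with the
    transcript/gene overlap decomposition, tumour- and metastasis-specific
    transcript calling, isoform-switch event detection, and a random-forest
    biomarker-panel evaluation harness. Includes a seeded synthetic-data
    generator with planted ground truth that exercises every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
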