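Package: cnvresp
Title: Copy-Number Variation Association with TNF-alpha Blocker Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of copy-number variation (CNV) and response
    to TNF-alpha blocker therapy in rheumatoid arthritis. Provides a
    simplified hidden Markov model caller that decodes integer copy number
    from SNP-array log R ratio (LRR) and B-allele frequency (BAF) signals,
    multi-sample segmentation of overlapping CNV calls at all observed
    boundaries into a samples-by-segments copy-number matrix, segment
    filtering by carrier frequency and a Hardy-Weinberg exact test,
    DAS28-ESR and CDAI disease-activity scoring with EULAR response
    classification, and covariate-adjusted logistic and linear association
    testing under Benjamini-Hochberg false-discovery-rate control. A seeded
    synthetic-cohort generator with a planted deletion effect makes every
    stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
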