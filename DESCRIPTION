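Package: arfclass
Title: Classification of ETT/ARF4 Regulatory Targets from Factorial RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers regulatory-model classes of transcription-factor targets
    from a factorial RNA-seq design (four genotypes crossed with two auxin
    treatments), as used to dissect the distinct, redundant and joint targets
    of the B-class auxin response factors ETT/ARF3 and ARF4 in the
    Arabidopsis gynoecium. Provides median-of-ratios normalization,
    method-of-moments negative-binomial dispersion estimation, a Wald test
    for group contrasts with Benjamini-Hochberg correction, three- and
    four-way Venn partitioning of differentially expressed gene sets,
    classifiers for auxin-independent targets and for conformance to A-B ARF
    antagonism models, hypergeometric over-representation analysis against an
    expressed-gene background, PCA-based quality control, and a seeded
    negative-binomial count simulator with planted regulatory classes and
    ground-truth labels for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
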