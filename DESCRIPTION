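Package: progsyn
Title: Genetic-Interaction Synergy and Aging-Signature Statistics for
    Progeroid Knockout Cohorts
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis toolkit for double-knockout progeria
    studies. Implements Bliss-independence synergy inference on
    time-resolved lesion incidence (expected combined incidence, synergy
    score time-courses, percentile-bootstrap confidence intervals and
    resampling-based p-values), Kaplan-Meier lesion-free survival with
    log-rank comparison and fixed-horizon incidence estimation, and the
    downstream transcriptome statistics used in aging-signature work:
    expression and differential-expression filters, Benjamini-Hochberg
    adjustment, a signed ranking metric, pre-ranked gene-set enrichment
    (weighted Kolmogorov-Smirnov running sum with gene-label permutation),
    transcript-length imbalance testing, cross-tissue core signatures and
    marker-based immune scoring. A deterministic synthetic-data generator
    emulates four-genotype cohorts with tunable genetic interaction and
    differential-expression tables with planted signal, so every stage is
    testable without access to animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
biocViews: Survival, GeneSetEnrichment, DifferentialExpression, Software
RoxygenNote: 7.3.3
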