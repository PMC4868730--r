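Package: mutexpress
Title: Expression-Associated Somatic Mutation Scanning and Driver
    Prioritization for Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for genome-wide somatic mutation-expression
    association studies in tumor cohorts. Residualizes relative transcript
    abundance on copy-number and methylation determinants, scans all
    SNV-gene pairs for expression-associated single-nucleotide variants
    (eSNVs) with multiplicity control and genomic-control diagnostics,
    ranks mutated genes by network propagation to separate drivers from
    passengers, clusters patients by sparse mutation profiles with
    spherical k-means, evaluates prognostic value via Cox models,
    time-dependent ROC and censoring-adjusted concordance, integrates
    seven evidence criteria into a per-variant risk score, nominates
    synthetic-lethal partners from bimodal expression, and tests
    drug-target enrichment for repurposing. Ships a synthetic multi-omic
    cohort generator with implanted ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
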