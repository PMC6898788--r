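Package: icbResist
Title: Integrative Modeling of Intrinsic Resistance to Anti-PD1 Checkpoint
    Blockade in Melanoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative clinical-genomic-transcriptomic analysis of
    response to anti-PD1 immune-checkpoint blockade in melanoma cohorts.
    Implements a Monte-Carlo power calculation for somatic mutation detection
    used as a per-sample quality-control filter, whole-exome scalar features
    (tumor mutational burden, clonality-based heterogeneity, allelic aneuploidy
    fraction), transcriptome preprocessing and rank-based enrichment scoring
    (single-sample and cohort-level gene set enrichment with gene-set
    permutation nulls), contingency and survival statistics including adjusted
    odds ratios and interaction tests, forward-selected logistic models of
    progressive disease with cross-validated AUC and label-permutation empiric
    p-values, a stratified permutation test for subgroup-specific pathway
    enrichment, and a synthetic cohort generator that reproduces the marginal
    clinical and genomic structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    fgsea
Config/testthat/edition: 3
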