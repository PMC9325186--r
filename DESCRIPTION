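Package: besig
Title: Paired TMT (Phospho)Proteomic Differential Analysis and Disease Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of multiplexed (TMT) quantitative proteomic and
    phosphoproteomic cohorts with paired disease/adjacent-normal biopsies, built
    around the Barrett's esophagus study design: localization filtering, log2
    transformation and quantile normalization; paired empirical-Bayes moderated
    t-tests with Benjamini-Hochberg adjustment; disease-signature selection
    (top-percentile by p-value intersected with a fold-change floor) with a
    sign-flip randomization empirical FDR; unsupervised cross-cohort
    classification by hierarchical clustering on the signature, including
    projection onto transcriptome profiles; preranked permutation gene-set
    enrichment; and kinase-substrate enrichment z-scores. A seeded synthetic
    two-cohort generator with known ground truth makes every stage testable
    without access to raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
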