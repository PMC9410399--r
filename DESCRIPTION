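Package: edcassoc
Title: Case-Control Association, Gene-Gene Interaction and Biomarker
    Analysis for Epidermal Barrier Gene Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Statistical pipeline for candidate-gene case-control studies of
    atopic eczema and eczema-associated asthma in young children.  Implements
    Hardy-Weinberg goodness-of-fit testing, genetic-model exposure coding
    (dominant, recessive, allele, genotype trend), crude and covariate-adjusted
    odds ratios with Woolf confidence intervals, FLG-stratified and severity
    analyses, gene-gene interaction on the additive scale (relative excess risk
    due to interaction, attributable proportion, synergy index) and the
    multiplicative scale (ratio of relative risks, logistic product-term test),
    and predictive-biomarker metrics (sensitivity, specificity, predictive
    values with exact binomial intervals).  A synthetic-cohort generator with
    genotypes drawn under Hardy-Weinberg equilibrium and logistic disease
    models makes every stage testable without subject-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
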