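Package: metaboflow
Title: Two-Group Untargeted Metabolomics Analysis Workflow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A tested, reusable statistical workflow for two-group
    untargeted LC-MS metabolomics studies with plasma and urine sampled
    over time. Implements sum-normalization and Pareto scaling,
    Pareto-scaled PCA, single-response orthogonal projections to latent
    structures discriminant analysis (OPLS-DA) with stratified k-fold
    cross-validated Q2, R2Y, permutation-tested probabilities and variable
    importance for the projection (VIP), differential-metabolite screening
    (VIP > 1 and P < 0.05 with normality-gated univariate tests), ion-mode
    merging, endogenous/exogenous origin classification, hypergeometric
    pathway over-representation with differential-abundance (DA) scores,
    K-means clustering of longitudinal pathway trajectories with
    monotone-cluster selection, metabolite-phenotype Pearson correlation
    with multi-phenotype intersections, and cross-biofluid conjoint
    concordance analysis. Ships a synthetic-study generator with full
    ground truth so every stage is testable without raw spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
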