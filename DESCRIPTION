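Package: bilicausal
Title: Genetic Association and Mendelian Randomization Workflow for Serum
    Bilirubin and Hypertension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end statistical workflow linking a common UGT1A1-class
    variant to serum total bilirubin and, through bilirubin, to hypertension
    risk. Provides a synthetic cohort generator with linkage-disequilibrium
    blocks, population structure and cryptic relatedness; mixed-model
    genome-wide association with kinship random effects (EMMAX-style),
    rank-based inverse normal transformation, Tracy-Widom selection of
    ancestry principal components, genomic control and conditional analysis;
    Bayes-factor fine mapping with annotation-informed priors and posterior
    inclusion probabilities; REML SNP heritability with LD-informed variant
    weights; additive Bayesian network structure learning over mixed
    Gaussian/logistic nodes with majority-consensus edges; and two-stage
    least-squares Mendelian randomization with instrument diagnostics,
    inverse-variance-weighted meta-analysis and analytic power for binary
    outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
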