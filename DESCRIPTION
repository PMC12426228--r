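Package: msexposome
Title: Multidimensional Social Exposome Modelling for Aging and Dementia Cohorts
Version: 0.1.0
Authors@R: person("Exposome", "Toolkit", email = "tools@example.org", role = c("aut", "cre"))
Description: Builds multidimensional social exposome (MSE) composite scores from
    questionnaire items (chained predictive-mean-matching imputation, min-max
    scaling, polarity handling, dimension averaging), fits a one-factor
    structural equation model in which ten adversity dimensions load on a
    latent exposome factor predicting cognition, functional ability and
    neuropsychiatric symptoms (maximum-likelihood covariance-structure
    estimation with CFI/TLI/RMSEA/SRMR fit indices, modification indices,
    factor scores and case-resampling bootstrap), compares the cumulative
    latent score against individual dimensions via Lasso regression and
    fixed-effect meta-regression, reproduces group-level summary statistics
    (one-way ANOVA from summary data, chi-square tests, pooled moments), and
    associates resting-state connectome edges with the exposome score using
    per-region false-discovery-rate control, binarized degree centrality and
    motion/signal quality control. Includes seeded synthetic-cohort
    generators emulating the assumed latent structure so the full pipeline is
    testable without access to restricted raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), glmnet, jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
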