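Package: proxyGxEMR
Title: Proxy Gene-by-Environment Mendelian Randomization for Maternal Exposures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for proxy gene-by-environment Mendelian randomization, in
    which offspring genotype stands in for an unmeasured maternal genotype and
    analyses are stratified on a maternal environmental exposure (the
    motivating application is maternal smoking heaviness in pregnancy and
    offspring left-handedness). Provides a synthetic mother-offspring cohort
    generator with Mendelian transmission, pleiotropy and collider scenarios;
    univariable and multivariable logistic regression with seasonal month
    encoding and McFadden pseudo R-squared; polygenic risk score construction
    by p-value thresholding, greedy LD clumping and allele harmonization;
    Wald-ratio causal estimation with delta-method standard errors and
    pleiotropy correction by between-stratum subtraction; positive and
    negative control checks; and Monte-Carlo power, bias, coverage and
    collider-bias simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
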