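Package: bayesgl
Title: Genomic Prediction with Global-Local Shrinkage Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome Bayesian regression for genomic prediction with
    global-local shrinkage priors: the Horseshoe (BayesU), the Horseshoe+
    (BayesHP) and a half-t local prior with an unknown, Metropolis-Hastings
    sampled degree of freedom (BayesHE), alongside the classical comparison
    models GBLUP (VanRaden genomic relationship matrix, EM-REML variance
    components), BayesA and BayesB. Includes genotype/phenotype IO with
    quality-control filters, a pedigree/gene-dropping simulator of
    QTL-MAS-style data sets, and a cross-validation harness with the
    accuracy and bias metrics used in dairy-cattle genomic evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
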