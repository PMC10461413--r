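Package: archwalk
Title: Genetic Architecture of Quantitative Traits Under Contrasting
    Demographic and Selective Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to compare the genetic architecture of a quantitative
    trait between populations with contrasting demographic and selective
    histories, such as a large long-established population under
    stabilizing selection and small recently founded populations under
    strong directional selection.  Provides linear mixed-model
    association with a centered kinship matrix, Lindley local-score
    aggregation of association p-values into candidate loci, LD-based
    clumping and pruning, maximum-likelihood comparison of exponential
    versus uniform effect-size distributions, diversity-based effective
    population size, a neutral expectation for allele age, and a forward
    Wright-Fisher simulator with partial selfing, colonization
    bottlenecks and a shifting trait optimum for generating synthetic
    study populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
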