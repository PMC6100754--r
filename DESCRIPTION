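Package: mrsynth
Title: Bayesian Cross-Species Synthesis of Restricted Mean Survival Time Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines survival evidence from human and animal studies of an
    intervention through the restricted mean survival time (RMST) ratio.
    Provides Kaplan-Meier and RMST estimation with Greenwood-type standard
    errors, Bayesian random-effects pooling of study-level log-ratios, a
    catalogue of skeptical, relational, mechanistic and enthusiastic prior
    specifications over species and intervention effects, a
    Metropolis-within-Gibbs sampler for the two-way hierarchical
    species-by-intervention model, deviance information criterion and entropy
    model comparison, and simulators for end-to-end validation with known
    ground truth. The shipped application is the synthesis of ketogenic
    therapy (ketogenic diets and calorie restriction) survival data in
    high-grade glioma across humans, three mouse strains and rats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite
Config/testthat/edition: 3
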