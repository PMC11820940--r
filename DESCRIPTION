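Package: topsel
Title: Balanced Top- and Bottom-Line Selection for Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selection of top- (or bottom-) performing lines in genomic
    prediction framed as a classification problem.  Implements the GBLUP
    regression selectors (count-matching RC, fixed-quantile-threshold R and
    the sensitivity-specificity-balanced RO), the Bayesian probit threshold
    GBLUP selectors (fixed 0.5 rule B and the balanced BO), and the "Simple"
    single-fit variants of the tuned methods.  Ships a VanRaden genomic
    relationship matrix builder, Gibbs samplers for the linear and probit
    threshold models, a nested 5x10 cross-validation benchmark harness with
    Cohen's kappa, sensitivity, specificity, precision and F1 metrics,
    relative-efficiency reporting, and a seeded synthetic marker/phenotype
    generator with known heritability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
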