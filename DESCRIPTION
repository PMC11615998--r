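Package: nihlscreen
Title: Extreme-Group Selection of Noise-Induced Hearing Loss Susceptible and
    Resistant Workers
Version: 0.1.0
Authors@R:
    person("NIHL", "Screening Contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for identifying workers susceptible or resistant to
    occupational noise-induced hearing loss (NIHL) from cross-sectional
    audiometric surveillance data. Implements six published extreme-group
    selection procedures (stratified percentile cuts, bidimensional
    standardized-threshold cuts, linear and quadratic dose-residual cuts, and
    a machine-learning misclassification-based selector built on AdaBoost,
    multilayer perceptron, random forest and support vector machine
    classifiers), a cross-validated protocol for ranking audiometric
    frequency combinations including the extended high frequencies, a
    face-validity assessment that scores each method's susceptible and
    resistant groups against established risk-factor directions, and group
    characterization with zero-intercept hearing-loss growth slopes. A
    synthetic occupational-cohort generator with a planted latent
    susceptibility factor provides ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
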