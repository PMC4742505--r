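Package: coverdiag
Title: Coverage Diagnostics for Confidence Interval Procedures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying what a confidence procedure does and does not
    guarantee. Implements the uniform-location ("lost submarine") model with
    five 50% interval procedures (trivial, sampling-distribution,
    nonparametric, uniformly most powerful, objective Bayes), grid posteriors
    under arbitrary priors, and exact conditional-coverage and false-value
    inclusion computations; a generic Monte-Carlo harness for coverage,
    conditional coverage on relevant subsets, inclusion curves and width
    profiles; and the noncentral-F test-inversion confidence interval for the
    one-way ANOVA effect size omega squared, with bound-existence flags,
    likelihood curves, grid Bayesian highest-posterior-density intervals and a
    synthetic one-way ANOVA generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
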