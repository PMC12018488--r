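Package: pragsub
Title: Pragmatic Subgroup Discovery for Heterogeneous Treatment Effects
Version: 0.1.0
Authors@R:
    person("pragsub", "developers", email = "pragsub@example.org", role = c("aut", "cre"))
Description: Two-step workflow for heterogeneous treatment effect analysis in
    two-arm randomized trials. Step 1 estimates per-subject conditional average
    treatment effects (CATEs) on the risk-difference scale with an honest
    two-arm tree-ensemble meta-learner, inverse-probability-of-censoring
    weights, and calibration diagnostics (Qini curve and coefficient,
    C-for-benefit with bootstrap confidence intervals). Step 2 recodes raw
    covariates into interpretable clinical categories via a declarative
    ruleset, discovers mutually exclusive subgroups with a depth-limited CART
    regression tree on the estimated CATEs, and validates each subgroup with
    augmented inverse probability weighted (AIPW) risk differences. Includes a
    synthetic randomized-trial generator with planted, subgroup-structured
    effect heterogeneity and covariate-dependent censoring for end-to-end
    testing, plus a config-driven pipeline and command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
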