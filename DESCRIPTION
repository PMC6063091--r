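Package: gremlspectra
Title: Spectral Analysis of Random-Effects Heritability Estimators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the statistical behaviour of GREML-type
    random-effects estimates of SNP heritability through the eigenvalue
    spectrum of the genetic relatedness matrix. Provides the rotated-
    coordinate profile likelihood and its score equation, the maximum
    likelihood estimator of heritability with negative estimates allowed,
    closed-form bias and variance approximations driven by spectral
    tau-moments, analytic moment calculators for Marcenko-Pastur, paired
    point-mass, dosage-mixture and lognormal eigenvalue laws, analyses of
    model misspecification (restricted causal subsets, untagged causal
    variants, measurement error, GRM inversion symmetry), and seeded
    simulation generators that validate every approximation by Monte Carlo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
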