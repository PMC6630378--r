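Package: pedpk
Title: Pediatric Population Pharmacokinetics with Size and Maturation Functions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear mixed-effects population pharmacokinetic modelling for
    pediatric cohorts. Provides linear one- to three-compartment structural
    models with intravenous bolus, infusion and first-order oral dosing,
    allometric size scaling and sigmoid-Emax organ-maturation functions on
    structural parameters, FOCE-with-interaction estimation with an adaptive
    Gauss-Hermite quadrature oracle, likelihood-ratio model comparison,
    conditional weighted residuals, visual predictive checks, nonparametric
    bootstrap, stepwise covariate modelling, and a synthetic-study generator
    emulating three pediatric trial designs (cyclosporine A, phenobarbital,
    vancomycin).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    pracma,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    yaml
Config/testthat/edition: 3
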