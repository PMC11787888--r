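Package: hsrsim
Title: Human-Simulated Antibiotic Regimens in Murine Plasma and Epithelial
    Lining Fluid
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing and confirming human-simulated antibiotic
    dosing regimens (HSRs) in murine pneumonia models. Provides closed-form
    one-compartment first-order-absorption pharmacokinetic simulation with
    multi-dose superposition and periodic steady state, PK/PD exposure
    metrics (percent fT>MIC across MIC doubling dilutions, unbound Cmax and
    AUC), matrix corrections (ultrafiltration free fraction, BAL urea-dilution
    estimation of epithelial lining fluid concentrations, plasma-to-ELF
    penetration regression), naive-pooled nonlinear least-squares parameter
    estimation with AIC model selection and interquartile-range outlier
    filtering, an exposure-matching regimen optimizer, and a seeded generator
    of realistic sparse murine PK study datasets. Ships the fitted murine
    parameters, dosing schedules and human reference exposures for meropenem,
    cefiderocol and tobramycin as a validated configuration fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
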