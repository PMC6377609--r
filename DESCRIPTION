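Package: zfpk
Title: Pharmacokinetic Modelling of Waterborne Compounds in Developing
    Zebrafish Larvae
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Compartmental pharmacokinetic analysis of internal exposure to
    waterborne compounds in zebrafish larvae, using paracetamol as paradigm
    compound. Implements one- and two-compartment structural models with
    zero-order absorption and first-order or Michaelis-Menten elimination,
    age (days post fertilisation) covariate models on the absorption and
    elimination rate constants, maximum-likelihood estimation under additive,
    proportional or combined residual-error models, likelihood-ratio-test
    model selection, goodness-of-fit diagnostics, design-faithful synthetic
    data simulation, clearance derivation from elimination rate constants and
    larval volumes, and allometric interspecies scaling of clearance against
    bodyweight.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
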