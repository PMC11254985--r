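Package: apopkpd
Title: Population PK/PD Trial Simulation for On-Demand Apomorphine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based comparison of subcutaneous and sublingual apomorphine
    for aborting OFF episodes in Parkinson's disease. Implements the published
    compartmental pharmacokinetic models for both formulations (one-compartment
    first-order absorption for subcutaneous; transit-chain absorption into a
    two-compartment disposition model for sublingual), an effect-compartment
    link driving a sigmoid-Emax model of the UPDRS Part III motor score, and a
    Monte-Carlo clinical trial simulator with lognormal inter-individual
    variability. Extracts exposure metrics (AUC, Cmax, Tmax) and
    threshold-based clinical response endpoints per simulated subject, and
    summarizes them over a dose x formulation x variability grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    Matrix,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    jsonlite
Config/testthat/edition: 3
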