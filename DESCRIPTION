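Package: gravipk
Title: Pharmacokinetic Translation for Pregnant Patients with Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic translation of drug pharmacokinetics between healthy,
    cancer, and pregnancy physiologies. Provides population physiology scalers
    with gestational-week interpolation, a two-protein (albumin and
    alpha-1-acid glycoprotein) plasma binding model, well-stirred hepatic
    clearance back-calculation and prediction from enzyme abundance, fraction
    unbound and glomerular filtration, a two-compartment kinetics engine for
    intravenous infusion and oral dosing, noncompartmental analysis, virtual
    clinical trials with lognormal inter-individual variability, predictive
    performance metrics (two-fold criterion, 90 percent prediction interval),
    a population-model selection workflow, and a synthetic sparse clinical
    dataset generator. Bundled models for paclitaxel, docetaxel and
    acalabrutinib are calibrated to published exposure anchors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
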