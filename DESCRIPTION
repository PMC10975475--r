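Package: pktranslate
Title: Preclinical-to-Human Pharmacokinetic Translation and Whole-Body
    PBPK Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for translating preclinical pharmacokinetic studies of a
    small-molecule drug candidate into first-in-human predictions. Derives
    model constants from in vitro assays (Caco-2 permeability, equilibrium
    dialysis, hepatocyte depletion) and tissue distribution studies, performs
    non-compartmental analysis of concentration-time data, fits one-compartment
    oral absorption models, predicts human clearance and volume of distribution
    by interspecies allometric scaling (single-species, fu-corrected,
    two-species, fu-corrected intercept and hepatic blood flow methods plus the
    Oie-Tozer method), computes first-in-human starting doses by the
    body-surface-area and systemic-exposure methods, and simulates plasma and
    liver concentration-time profiles with a whole-body perfusion-limited
    physiologically based pharmacokinetic (PBPK) model featuring
    Rodgers-Rowland tissue partitioning, biliary clearance and enterohepatic
    recirculation. Includes seeded synthetic study generators mirroring the
    supported preclinical study designs.
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
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
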