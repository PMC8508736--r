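Package: musclesim
Title: Modular Multi-Level Simulation of Exercising Human Skeletal Muscle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulator of human skeletal muscle during aerobic exercise,
    built from a port-based modular modelling formalism that composes
    capillary-blood physiology, inter-compartment metabolite transport,
    two-fiber-type energy metabolism, Ca2+/CaMKII and AMPK-heterotrimer
    signalling, and early/delayed exercise-responsive gene expression into
    one flat hybrid ordinary-differential-equation system. Exercise is
    driven by configurable ramp, interval and continuous protocols with
    fiber-type recruitment and optional fatigue-as-power-decline. Includes
    a text dialect for annotated species notation, SBML export of
    flattened models, and derived observables (muscle pH, phosphorylation
    fractions, mRNA fold changes, mixed-muscle averages).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
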