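Package: permaflow
Title: Equilibrated Caco-2 Permeability Analysis and Transwell Assay Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bidirectional Caco-2 transwell permeability
    assays run close to steady state (pre-incubated, BSA-supplemented
    "equilibrated" protocol). Computes apparent permeability (Papp), efflux
    ratio and mass-balance recovery from well-level LC-MS peak-area read-outs,
    qualifies results against detection-limit, recovery and replicate
    variability rules, back-calculates approximated intestinal absorption
    (fafg) from rodent intravenous/oral pharmacokinetic summaries, classifies
    compounds by Lipinski/bRo5 status and permeability/efflux cut-offs, and
    evaluates cut-off-based absorption prediction with confusion matrices. A
    mechanistic compartmental transwell simulator with cell-loading lag,
    plastic adsorption and detection-limit censoring provides ground-truth
    labelled synthetic cohorts for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
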