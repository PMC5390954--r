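Package: idsplan
Title: Interactive Dose Shaping for IMRT Treatment Planning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interactive dose shaping (IDS) in intensity-modulated
    radiation therapy planning. Implements local dose modification via
    minimum-norm fluence patches with a budgeted recovery step (the DMR
    operator), a finite pencil-beam dose-influence engine with incremental
    dose evaluation, seeded synthetic pelvic phantoms (PTV with
    simultaneous integrated boost, rectum, bladder), a hierarchical
    goal-driven shaping loop with a quadratic-penalty baseline optimizer,
    plan-quality mathematics (DVH, dose/volume indicators, conformity and
    homogeneity indices, non-tumor integral dose, Quantec constraint
    report), and fluence stratification with step-and-shoot MLC sweep
    sequencing including an exact-reconstruction deliverability check.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
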