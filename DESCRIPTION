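Package: ffrnet
Title: Noninvasive Fractional Flow Reserve from Lumped Coronary Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes fractional flow reserve (FFR) noninvasively from a
    reduced-order resistive-network model of the coronary tree. Resting
    coronary flow is distributed over the epicardial branches by an
    allometric diameter power law, microcirculatory outlet resistances are
    calibrated from Poiseuille pressure drops at rest, hyperemia is imposed
    through clinical scaling statistics, and the hyperemic outlet flows are
    identified by an under-relaxed fixed-point iteration that couples
    stenotic resistance, microcirculation resistance and inlet pressure.
    Includes a diameter-flow comparator method, a synthetic cohort
    generator, and diagnostic-performance statistics (confusion matrix,
    sensitivity, specificity, predictive values, Bland-Altman limits of
    agreement, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
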