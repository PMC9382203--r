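Package: thermoramp
Title: Cardiorespiratory Analysis of Thermal-Ramping Respirometry in Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing acute thermal-ramping trials in fish under
    different water oxygenation regimes: intermittent stop-flow respirometry
    slope analysis with background-respiration correction, pulsatile
    ventral-aortic blood-flow analysis (heart rate, cardiac output, stroke
    volume) with Fick-estimated arteriovenous oxygen content difference,
    critical thermal maximum (CTmax) group statistics including mixed
    two-way ANOVA with Greenhouse-Geisser adjustment and exact Mann-Whitney
    tests, LT50 sigmoidal fits, and a literature synthesis of
    hyperoxia-induced thermal tolerance. A synthetic-trial generator with
    ground-truth sidecars makes every stage testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
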