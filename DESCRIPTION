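Package: arcplan
Title: Automated Single-Arc VMAT Planning and Plan Evaluation on Synthetic
    Pelvic Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Script-style fully automated volumetric modulated arc therapy
    (VMAT) planning for locally advanced rectal cancer at desk scale:
    seeded synthetic pelvic phantoms (density grid plus structure set),
    anisotropic margin expansion and optimization-ROI derivation, a
    simplified linear pencil-beam arc dose engine, staged fluence
    optimization with dose fall-off objectives, hotspot correction and
    target-coverage escalation, and a complete plan-evaluation toolbox
    (DVH metrics, conformity and homogeneity indices, clinical-goal
    reports, plan sums, 3%/2mm gamma analysis, modulation complexity
    score, exact Wilcoxon signed-rank comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tibble,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
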