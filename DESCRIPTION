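Package: wwtpopt
Title: Multi-Objective Optimization of an Activated-Sludge Wastewater
    Treatment Plant with Slime-Mould Metaheuristics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Dynamic simulation of a modified A2O (anaerobic-anoxic-oxic)
    activated-sludge plant built from the IWA Activated Sludge Model No. 2d
    biokinetics coupled to a ten-layer Takacs secondary settler, with
    synthetic dynamic influent generation and fractionation of measured
    indicators (COD, TN, TP, NH4-N, SS) into model components. Provides
    effluent-quality, energy/cost and volume objectives, sensitivity-driven
    kinetic-parameter calibration, single-objective (ISMA) and
    multi-objective (CRFSMA) slime-mould optimizers with reference-point
    non-dominated sorting, and an IGD benchmarking harness on the ZDT, DTLZ
    and UF analytic test suites.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
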