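Package: zfpk
Title: Pharmacokinetics of Fluorescent Compounds in Zebrafish Eleuthero-Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-body fluorescence pharmacokinetics in
    zebrafish eleuthero-embryos. Implements a one-compartment amount/fluorescence
    model with passive medium exchange (closed form and ODE oracle), nonlinear
    least-squares estimation of FLUOR, ke and Q with residual-based censoring of
    quench-affected observations, AUC-based Relative Exposure and Relative
    Contribution metrics, quantitative structure-pharmacokinetic (QSPkR)
    regression on molecular descriptors with a centered-quadratic LogD term,
    shake-flask LogD calculation with calibration QC gates, and integrated
    fluorescence quantification from images and body-contour masks. Includes a
    seeded synthetic-data generator emulating the multi-route study design so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
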