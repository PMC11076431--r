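Package: ufdce
Title: Ultrafast DCE-MRI Kinetics and Scan-Duration Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for ultrafast dynamic
    contrast-enhanced breast MRI. Generates synthetic lesion cohorts from an
    extended Tofts model driven by a population arterial input function,
    renders spoiled-gradient-echo signal volumes with Rician noise, converts
    signal to contrast-agent concentration via two-point variable-flip-angle
    T1 mapping, computes semi-quantitative kinetic parameters (maximum slope
    and initial area under the curve) on truncated dynamic series of
    increasing scan duration, and evaluates benign-versus-malignant
    diagnostic performance with ROC analysis, DeLong tests, Youden cutoffs,
    paired cross-duration comparisons and intraclass correlation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
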