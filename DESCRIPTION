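Package: vffr
Title: Virtual Fractional Flow Reserve from Intravascular Lumen Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes virtual fractional flow reserve (FFR) pullback curves
    from coronary lumen geometry using a reduced-order pressure-drop model
    (Poiseuille friction plus Borda-Carnot expansion loss) with a 1D
    finite-volume steady solver as an internal cross-check. Includes a
    classical minimal-path tracer for lumen contours on polar intravascular
    ultrasound images, ECG-gated pullback mapping, anatomical stenosis
    quantification (MLA, MLD, DS%, AS%, plaque burden), a full diagnostic
    performance layer (confusion-matrix indices with exact and logit
    confidence intervals, likelihood ratios, Youden-optimal cutoffs,
    ROC/AUC, Bland-Altman agreement), and seeded synthetic-data generators
    for vessels, polar image stacks, ECG trains and correlated paired
    cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    igraph,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
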