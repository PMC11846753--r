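Package: plaquemech
Title: Coronary Plaque Erosion Biomechanics and Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Desk-scale biomechanical analysis of coronary plaques with and
    without erosion. Processes segmented vessel cross-section contours
    (thrombus removal, outer-boundary completion, lipid trailing-edge
    construction, four-quarter-even-spacing resampling) into morphology
    metrics (area stenosis, plaque burden, cap thickness), evaluates
    modified Mooney-Rivlin constitutive models and a quasi-static
    thick-walled-tube surrogate for plaque wall stress and strain, a
    Poiseuille-based surrogate for lumen flow shear stress, and runs the
    downstream statistics: group and erosion-site comparisons with exact
    Wilcoxon tests, and logistic-regression erosion prediction with
    leave-one-out cross-validation and bootstrap AUC confidence intervals.
    Includes a synthetic cohort generator so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
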