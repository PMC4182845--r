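Package: mulchres
Title: Mulch Residue Estimation from Field Images by Saturation-Plane
    Thresholding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the deterioration of agricultural mulch films
    (polyethylene, biodegradable plastic, paper) from color field
    photographs. Images are converted from RGB to HSV, the saturation
    plane is binarized by one of four thresholding methods (Otsu,
    Ridler-Calvard isodata, co-occurrence local entropy, or a manual
    threshold), small noise regions are removed by 8-connected
    component analysis, and the percentage of bare-soil (white) pixels
    measures how much mulch has disappeared. Includes the statistical
    comparison layer used to vet the methods (paired t / Wilcoxon tests
    with a Shapiro-Wilk normality gate, one-way ANOVA with Duncan's
    multiple range test), a packaged per-image field dataset, and a
    synthetic two-class scene generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    stats,
    tools,
    utils,
    png
LinkingTo: Rcpp
Suggests:
    EBImage,
    optparse,
    jsonlite,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
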