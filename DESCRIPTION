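Package: lactospec
Title: Variable Cluster-Support Vector Machine Classification of Milk NIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric classification of UHT cow-milk near-infrared absorbance
    spectra (1350-2558 nm) into EU fat-content classes (skimmed, semi-skimmed,
    whole, no-class). Implements standard normal variate and Savitzky-Golay
    derivative pre-treatments, VARCLUS-style divisive variable clustering with
    first-principal-component cluster scores, tuned linear and radial-basis
    kernel support vector machine classification, one-vs-all confusion-matrix
    metrics (sensitivity, specificity, Matthews correlation coefficient), and a
    seeded synthetic milk-spectra generator so the full pipeline is testable
    without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
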