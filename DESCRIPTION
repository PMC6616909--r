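Package: isocomp
Title: Component-Model Prediction and Fitting of Moisture Sorption Isotherms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts moisture sorption isotherms of plant materials from
    their proximate chemical composition by combining vacuole (sugar and
    ash solution), fiber, starch and protein sub-isotherms, and fits the
    seven classical equilibrium-moisture-content equations (Henderson,
    Chung-Pfost, Halsey, Oswin, White-Eirig, Caurie, GAB) to measured or
    simulated water-activity data. Model comparison uses the coefficient
    of determination, the standard error of the model, the mean relative
    error, leave-one-out PRESS and a runs-test verdict on the residual
    pattern. Includes a synthetic equilibrium-relative-humidity data
    generator and a small command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
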