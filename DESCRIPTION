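Package: agarQuant
Title: Quantification of Arrayed Microbial Cultures on Agar Plates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the size, integrated optical density, granularity,
    colour and location of micro-organism cultures arrayed on solid agar
    from plate photographs. Corrects spatial lighting gradients by
    reconstructing a pseudo-empty plate and regressing pixel intensities
    towards the median agar intensity, then segments the corrected image
    with a two-component Gaussian mixture model of the intensity histogram,
    sensitive enough to detect dilute spotted cultures that are barely
    visible by eye. Per-culture timecourses are summarised with the
    logistic growth model. Includes a seeded synthetic plate-image
    generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    jpeg,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
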