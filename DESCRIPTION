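Package: ocplsnir
Title: One-Class Partial Least Squares Class Modelling of NIR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Untargeted detection of adulteration from near-infrared
    absorbance spectra by one-class partial least squares (OCPLS) class
    modelling: an uncentered NIPALS PLS1 regression of a constant response
    on spectra of the authentic class, with Monte-Carlo cross-validation
    for latent-variable selection and a normal-theory acceptance interval
    on the predicted response. Includes orthogonal-projection (against a
    water reference) and standard-normal-variate preprocessing, DUPLEX
    train/test partitioning, sensitivity/specificity evaluation with
    per-adulterant detection levels, a synthetic NIR study generator, and
    CSV/JCAMP-DX spectra input.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
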