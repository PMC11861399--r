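Package: archlength
Title: Cubic-Parabola Modelling and Prediction of Anterior Dental Arch Length
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the anterior dental arch (canine to canine through the
    incisal point) as a reflected third-degree parabola and computes its length
    by line integration of the arc-length integrand. Converts planned changes
    of incisor inclination and position, read from lateral cephalograms, into
    sagittal and vertical displacements of the incisal point by trigonometry,
    and from these predicts the post-treatment arch length. Includes a
    polyline measurement emulator, a synthetic-cohort generator with
    truncated-normal anatomy and additive measurement noise, and the agreement
    statistics used to validate the model against measured arch lengths:
    Lin's concordance correlation coefficient, intraclass correlation,
    Bland-Altman limits of agreement and absolute-difference summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
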