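Package: aortanorm
Title: Thoracic Aortic Normalcy Scores from Echocardiographic Diameters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assesses normalcy of the thoracic aorta measured by
    two-dimensional echocardiography at four levels (aortic annulus, sinuses
    of Valsalva, sinotubular junction, proximal ascending aorta). Provides
    two calculators trained on a healthy cohort: the conventional per-level
    Z-score from a single all-ages linear regression of diameter on
    normalized age, body surface area and sex, and the Q-score, a novelty
    detection score defined as the smallest percentile nu on a grid at which
    a nu-level one-class support vector machine flags the subject. Includes
    local (single-diameter) and global (four-diameter) Q-score variants, an
    optional saturating age correction, ROC/AUC comparison machinery with
    bootstrap confidence intervals and the DeLong test, stratified
    cross-validated scoring, and a synthetic cohort generator emulating the
    demographic and diameter structure of a healthy reference population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    pROC,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
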