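Package: apneaface
Title: Craniofacial and Acoustic Estimation of Sleep Apnea Severity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the Apnea-Hypopnea Index (AHI) of subjects
    suspected of obstructive sleep apnea from facial photographs and speech
    recordings. Implements three uncalibrated craniofacial measurements
    (cervicomental contour area, midface-to-interocular width ratio, and the
    tragion-ramus-stomion angle) computed from frontal and profile facial
    landmarks, an i-vector acoustic front-end (MFCC features, GMM universal
    background model, Baum-Welch statistics, MAP-adapted supervectors, and
    total-variability factor analysis), and support-vector regression of AHI
    under a leave-one-out protocol with an inner 5-fold hyperparameter grid
    search, including OSA classification from the estimated AHI.  A synthetic
    patient-cohort generator with planted effect sizes makes the whole
    pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
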