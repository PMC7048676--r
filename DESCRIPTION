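Package: nodulerisk
Title: Pulmonary Nodule Malignancy Probability Models and Their Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements four published logistic-regression calculators for the
    probability that a pulmonary nodule found on CT is malignant (Mayo Clinic,
    Department of Veterans Affairs, Peking University People's Hospital and
    Brock University models), together with a comparative-validation
    toolkit for judging them on a local population: batch scoring with
    applicability warnings, ROC/AUC with Hanley-McNeil confidence intervals
    on configurable diagnostic strata (benign vs malignant, early vs late
    stage, squamous and adenocarcinoma subsets), calibration curves,
    univariate screening of candidate predictors, and multivariate logistic
    refits reported as coefficient/odds-ratio tables. A seeded synthetic
    cohort generator emulates the structure of a hospital validation cohort
    (size, prevalence, diameter strata, feature prevalences, histology and
    stage mixes) with a planted outcome mechanism, so the whole pipeline can
    be exercised and property-tested end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    car,
    jsonlite,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
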