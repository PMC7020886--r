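Package: catstress
Title: Item Banking and Computerized Adaptive Testing for Stress Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and simulating a computerized adaptive test
    (CAT) of psychological stress under polytomous item response theory.
    Provides graded response, generalized partial credit and rating scale
    model probability, information and likelihood functions; marginal
    maximum likelihood (Bock-Aitkin EM) item calibration with -2LL/AIC/BIC
    model comparison; a five-filter item-bank screening pipeline
    (polychoric-correlation unidimensionality check, Yen's Q3 local
    independence, discrimination, Orlando-Thissen S-X2 item fit, and
    ordinal-logistic-regression DIF with McFadden pseudo-R2 and
    purification); a maximum-information CAT engine with EAP scoring and
    fixed-length or standard-error stopping rules; an evaluation battery
    (marginal reliability, correlations with the complete test and an
    external criterion, ROC/AUC); and seeded synthetic-data generators,
    including a packaged 20-item graded-response parameter fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
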