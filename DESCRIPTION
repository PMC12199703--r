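Package: agmix
Title: Partitioning Silver Nanoparticle Toxicity into Ionic and Particulate Contributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dose-response machinery for acute immobilization tests with
    Daphnia magna exposed to silver nanoparticle suspensions, and the
    response-additivity decomposition of suspension toxicity into ionic and
    particulate components. Fits four-parameter log-logistic curves with
    limits fixed at 0 and 1 by binomial maximum likelihood, estimates
    quasi-binomial overdispersion, compares EC50 values on the log-ratio
    scale, converts ICP-MS speciation measurements into per-concentration ion
    and particle doses, and reports toxic units and relative contributions at
    the suspension EC50. A synthetic-data generator reproduces the statistical
    structure of the experimental design for parameter-recovery simulation.
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
    optparse,
    yaml
Config/testthat/edition: 3
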