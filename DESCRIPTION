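Package: lifecourse
Title: Lifetime Morbidity and Healthcare Cost Projection from Stratified
    Discrete-Time Markov Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates gender- and age-stratified discrete-time Markov
    transition matrices over aggregated clinical risk group (CRG) health
    states from a longitudinal person-year panel, tests the stationarity
    (time-homogeneity) of the transition probabilities with a chi-squared
    statistic, projects morbidity over the whole life course both by exact
    cohort propagation and by Monte-Carlo microsimulation of individual
    birth-to-death pathways, attaches mean annual healthcare costs by
    gender and health state, and reports healthy-life-expectancy
    decompositions and lifetime-cost distributions. A synthetic-registry
    generator with a known ground truth supports testing and calibration
    when no individual-level registry is available.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
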