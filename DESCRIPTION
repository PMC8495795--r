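Package: evotraj
Title: Growth-Rate Trajectories and Repeatability Statistics for
    Serial-Transfer Evolution Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fitness trajectories from long-term
    serial-transfer evolution experiments assayed on microplate readers.
    Estimates maximum growth rates (doublings per hour) from kinetic
    optical-density curves by sliding-window log-linear regression, fits and
    compares linear, power-law and hyperbolic trajectory models with
    small-sample corrected AIC and evidence ratios, partitions growth-rate
    variance into genotype and replicate-within-genotype components to
    quantify the repeatability of evolution, and analyses correlated
    responses across assay temperatures (trade-off classification,
    evolution-by-assay temperature interaction, cross-temperature
    correlation) together with serial-transfer demography (generations per
    day, harmonic-mean effective population size).  A seedable simulator of
    the full experimental design generates synthetic optical-density curves
    and growth-rate trajectories with known ground truth, so every stage of
    the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
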