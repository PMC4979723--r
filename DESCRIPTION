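Package: reservaplan
Title: Systematic Conservation Planning Under Oil-Extraction Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale systematic conservation planning pipeline for
    landscapes contested between biodiversity protection and hydrocarbon
    concessions, modelled on the Ecuadorian Amazon. From stacked species
    distribution surfaces and a categorical ecosystem map it builds planning
    units, range-size-scaled conservation targets and an environmental-risk
    cost surface, then selects reserve networks by simulated annealing under
    three oil-block lock scenarios (Marxan-style minimum-set problem with
    summed-solution selection frequencies). Also provides richness mapping
    with upper-tertile richness centers, zonal overlap accounting, and a
    quartile-based oil-block conservation-importance index. A seeded
    synthetic-landscape generator makes every stage testable without
    external geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
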