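Package: careshed
Title: Travel-Time Accessibility of Childbirth Care Over Rugged Terrain
Version: 0.1.0
Authors@R: person("Careshed", "Maintainers", email = "maintainers@careshed.org",
    role = c("aut", "cre"))
Description: Models walking (and multimodal) travel time from a rural
    population to health facilities using two independent engines: an
    anisotropic raster cost surface driven by a Naismith-Langmuir walking
    rule with slope and land-use friction coefficients, and a virtual
    hexagonal/triangular mesh network merged with the mapped road network.
    Tabulates population coverage by travel-time bands, summarises facility
    staffing and delivery caseloads, and evaluates delivery-site reduction
    scenarios with a greedy maximal-coverage planner. Ships a seeded
    synthetic-district generator (terrain, land use, villages, roads,
    facilities) so the whole pipeline is exercisable without proprietary
    geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
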