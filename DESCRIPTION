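Package: corridorsim
Title: Cumulative-Effects Scenario Modelling of Wildlife Corridors and
    Human-Wildlife Conflict Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates multi-decade change in development footprint and
    recreational activity on a raster landscape, estimates grizzly bear
    movement connectivity with stochastic least-cost-path ensembles on a
    resource-selection-derived cost surface, and maps human-bear conflict
    risk under a business-as-usual forecast and mitigation scenarios.
    Includes a synthetic mountain-valley landscape generator so the full
    pipeline is reproducible without proprietary GIS or fitness-tracker
    inputs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
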