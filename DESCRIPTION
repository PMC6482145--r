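Package: reefbudget
Title: Census-Based Coral Reef Flat Carbonate Budgets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes census-based carbonate budgets for coral reef flats
    from point-intercept benthic surveys, chain-method rugosity
    measurements and echinoid belt transects. Gross carbonate production
    is estimated per survey line from percent cover, taxon- and
    morphology-specific calcification rates and a rugosity coefficient;
    bioerosion is decomposed into endolithic borer, parrotfish and
    echinoid components; net production (G, kg CaCO3 m-2 yr-1) is
    aggregated across survey lines, eco-geomorphic zones, radial
    transects and the whole reef. Includes a synthetic survey generator
    with recorded ground truth for validation, and a regression-based
    estimate of the live-coral-cover threshold at which the budget turns
    positive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
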