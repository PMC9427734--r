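Package: timbercities
Title: Land-Use Change and Carbon Accounting for Timber-City Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale scenario model of housing new urban dwellers in
    engineered-wood buildings and the consequences for land use and cumulative
    CO2 emissions to 2100. Couples an urbanization-driven timber demand model,
    age-class forest plantation dynamics with rotation by current annual
    increment, IPCC tier-1 first-order-decay harvested-wood-product carbon
    pools, and a signed land/manufacturing emission ledger, run over a
    BAU/10pc/50pc/90pc by SSP1/2/3 scenario matrix on seeded synthetic
    regional data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
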