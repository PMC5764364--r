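Package: hnccost
Title: Bottom-Up Costing and Package Rates for Head and Neck Cancer Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bottom-up (micro-)costing of hospital cancer services:
    equivalent annual cost annualization of capital, apportionment of shared
    resources across services, per-service unit costs, aggregation of patient
    out-of-pocket expenditure, multivariate probabilistic sensitivity analysis
    of resource prices, and composition of provider-payment package rates for
    head and neck cancer treatment. Includes a synthetic facility-data
    generator emulating a tertiary-care radiotherapy department so the whole
    pipeline runs end to end without access to confidential facility records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
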