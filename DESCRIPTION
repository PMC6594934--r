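Package: oxybox
Title: Box Model of the Coupled Ocean Oxygen-Nitrogen Cycle Under Long-Term Warming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-box ocean biogeochemistry model of the coupled oxygen,
    nitrate and phosphate cycles with denitrification and nitrogen fixation,
    together with the tracer-based oxygen-budget accounting (abiotic oxygen,
    preformed phosphate, true oxygen utilisation) needed to decompose
    long-term oxygen-inventory change into solubility, respiration and
    fixed-nitrogen-loss components. Includes a prescribed multi-millennial
    warming and overturning scenario generator, conservative forward-Euler
    integration with exact flux bookkeeping, and diagnostics for budget
    closure, suboxic volume, N* and the denitrification/nitrogen-fixation
    lag.
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
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
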