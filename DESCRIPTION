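Package: hemscost
Title: Full-Cost Simulation of Helicopter Emergency Medical Services
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic full-cost model for a helicopter emergency medical
    service (HEMS) station. Computes total annual cost from fixed,
    personnel, variable (fuel and medical material) and jump-fixed (step)
    maintenance components triggered by start counts, engine minutes and
    winch usages; allocates cost to primary missions through an area-based
    key to obtain average cost per primary mission; and performs break-even
    analysis against a per-engine-minute tariff, including detection of
    transient profitability lost to maintenance-interval jumps. Ships the
    fifteen built-in scenario variations (operating hours crossed with cost
    and equipment assumptions), scenario sweeps, cost-curve and break-even
    plots, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
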