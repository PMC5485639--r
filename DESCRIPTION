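Package: dairygap
Title: Yield-Gap Analysis for Smallholder Dairy Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and closing milk yield gaps in smallholder
    dairy systems. Combines three methods: top-decile benchmarking of
    attainable per-lactation milk yields from farm surveys; stochastic
    frontier analysis of a multi-output Cobb-Douglas output distance
    function with normal noise and half-normal inefficiency, giving
    per-farm technical efficiency scores and an inefficiency z-test; and a
    monthly bio-economic household herd simulator (energy/protein-limited
    milk production, reproduction, mortality, herd management and livestock
    profit) used to evaluate nutrition and genetics interventions. Gap
    reports integrate simulated yields with benchmarked attainable yields.
    Includes a synthetic-data module generating survey populations with
    known frontier truth and a shipped library of household scenarios for
    five agro-ecological regions of Ethiopia and India.
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
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
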