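Package: parasitherm
Title: Thermal Biology and Demography of Coffee Berry Borer Parasitoids
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for constant-temperature life
    history assays of coffee berry borer parasitoids (Prorops nasuta and
    Phymastichus coffea). Generates individual-level synthetic cohorts with
    stage-structured survival, temperature-dependent sex ratio, longevity
    and fecundity; runs nonparametric temperature comparisons
    (Kruskal-Wallis with Dunn's post hoc tests and compact letter
    displays) and logit-link survival models; fits linear
    development-rate models with lower developmental thresholds and
    thermal constants; computes age-stage two-sex life-table parameters
    (net reproductive rate, intrinsic and finite rates of increase,
    generation time, doubling time) with percentile-bootstrap confidence
    intervals; and estimates monthly and annual numbers of generations
    across temperature isotherms from a degree-day model.
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
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
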