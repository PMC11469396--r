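Package: mixrisk
Title: Source-to-Outcome Risk Mapping for Spatially Referenced Chemical Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates georeferenced populations, converts external air
    concentrations of chemical mixtures into in-vitro-equivalent tissue
    concentrations via inhalation dosimetry and steady-state toxicokinetics,
    fits two- and three-parameter Hill concentration-response models to
    high-throughput screening data by maximum likelihood, and quantifies
    mixture risk per simulated individual with generalized concentration
    addition (GCA), independent action (IA), and hazard quotients (HQ).
    Results are summarized as regional quantiles, including multi-assay
    quantile-of-quantile summaries, with one-at-a-time sensitivity analysis,
    ggplot2 visualizations, GeoJSON choropleth export, and a synthetic-data
    generator that emulates every required input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
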