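Package: leafoptim
Title: Optimality-Based Prediction of Leaf Traits Along Climate and
    Elevation Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts four photosynthesis-related leaf traits -- the ratio
    of leaf-internal to ambient CO2 partial pressure (chi), maximum
    carboxylation capacity standardised to 25 degrees C (Vcmax25), leaf
    mass per area (LMA) and leaf nitrogen per area (Narea) -- from
    growing-season bioclimate using eco-evolutionary optimality theory
    (the least-cost and coordination hypotheses and a leaf-economics
    model for deciduous LMA). Includes derivation of bioclimatic drivers
    from site metadata, re-calibration of the free regression
    coefficients, one-at-a-time attribution of between-site trait
    differences to individual environmental drivers, first-order and
    Monte-Carlo propagation of parameter uncertainty, model evaluation
    against observed trait tables, and a synthetic elevation-transect
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    broom,
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
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
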