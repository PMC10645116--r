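Package: paleowave
Title: Demographic Transitions and Growth Waves from Radiocarbon Summed
    Probability Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs deep-time human population dynamics from
    radiocarbon date tables. Calibrates conventional radiocarbon ages
    against IntCal-style calibration curves, builds summed probability
    distributions (SPDs) as relative population proxies, detects the major
    demographic transition in each series by least-squares structural-change
    search, extracts generational log reproductive rates and maximal waves
    of uninterrupted growth, and fits a cooperation/competition growth model
    (a Ricker map augmented with a hyperbolic Allee term) to each wave.
    Includes a synthetic-data generator that simulates population
    trajectories with regime shifts and forward-models radiocarbon samples
    from them, so breakpoint and parameter recovery can be tested end to
    end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
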