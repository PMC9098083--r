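Package: fidsim
Title: Escape-Behavior Models and Speed Sensitivity for Animal-Vehicle
    Encounters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative models of avian escape behavior applied to
    approaching vehicles: the perceptual limits hypothesis, the flush early
    and avoid the rush (FEAR) hypothesis with the phi index, the looming
    stimulus hypothesis, the visual cue model, and a Bayesian optimal escape
    model. Includes a Monte-Carlo simulation framework that generates alert
    distance and flight initiation distance (FID) data across a grid of
    vehicle approach speeds and FID-vs-speed slopes, estimates each model's
    sensitivity to approach speed via effect sizes (phi index, Cohen's f2),
    detects the slope window consistent with a spatial margin of safety, and
    computes the Critical Vehicle Approach Speed (CVAS) management metric.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
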