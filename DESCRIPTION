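Package: leaftrack
Title: Tracking Rhythmic Leaf Movement and Estimating Circadian Period
    from Time-Lapse Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for measuring circadian rhythms in plants
    from time-lapse photography. Image stacks are cropped into per-plant
    sub-stacks with a fixed grid, inter-frame motion is estimated by a
    differential (gradient-based) translation solve over each plant region,
    and the circadian period of the resulting vertical-motion time series is
    estimated by linear detrending, an FFT periodogram initial guess, and
    Nelder-Mead refinement of a single-frequency cosine. Includes a synthetic
    data module (decaying noisy cosine traces and oscillating-blob image
    sequences) for validation by parameter recovery, and quality-control
    filters for aggregating per-plant periods to per-line summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jpeg,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
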