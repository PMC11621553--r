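Package: calspike
Title: Quantification of Symbiotic Nuclear Calcium Spiking from Fluorescence Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify nuclear calcium spiking from genetically
    encoded calcium-indicator fluorescence time series: a sliding-window
    signal-to-noise (SNR) transform, threshold-based peak calling,
    per-nucleus frequency/amplitude/spiking summaries, region-of-interest
    quantification on confocal image stacks (sub-stack selection,
    z-projection, automatic thresholding, mean grey value, ROI trace
    extraction), and a reproducible statistical decision tree (normality
    and variance gates, log10/Box-Cox transforms, t tests, Mann-Whitney,
    one-way ANOVA with Tukey HSD, Kruskal-Wallis, Fisher exact). A
    synthetic-data module simulates indicator-like traces with
    photobleaching, Poisson-timed spikes and Gaussian noise, and toy image
    stacks with known foreground, so every stage is testable end to end
    against ground truth.
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
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
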