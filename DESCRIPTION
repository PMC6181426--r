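Package: meaplate
Title: Feature Extraction and Treatment Comparison for Multi-Well
    Microelectrode Array Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of neuronal spike-train recordings from multi-well
    microelectrode array (MEA) plates. Reads Axion-style spike lists and
    generic spike-time formats, detects electrode-level bursts (Maximum
    Interval and Poisson Surprise), well-level network spikes and
    Gaussian-smoothed/Otsu-thresholded network bursts, and computes
    synchrony metrics (spike time tiling coefficient, entropy, mutual
    information). Aggregates features across recordings of the same plate,
    filters inactive wells, and compares treatments with Mann-Whitney and
    label-permutation tests, plus earth mover's distance and maximum
    CDF-distance comparisons of burst-feature distributions. Includes a
    synthetic plate simulator with known ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
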