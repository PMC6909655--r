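Package: gdperf
Title: Goal-Directed Perfusion Analytics for Cardiopulmonary Bypass
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing oxygen delivery during cardiopulmonary bypass
    under the goal-directed perfusion (GDP) paradigm. Provides oxygen-transport
    calculators (arterial oxygen content, indexed oxygen delivery DO2i, Fick
    oxygen consumption, extraction ratio), a seeded generator of realistic
    multi-patient intra-operative time series, a cleaning and interpolation
    pipeline that merges per-patient records into one time-indexed analysis
    dataset, GDP constraint and measurement-density filters, iso-DO2i band
    extraction with weighted quadratic cardiac-index-versus-haemoglobin fits,
    pump-flow recommendation calculators, and plotting and cohort-summary
    helpers. All steps chain with the pipe and return tibbles.
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
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
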