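Package: hfqc
Title: Moving-Window Quality Control for High-Frequency Water-Quality Sensor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flags anomalies in high-frequency freshwater sensor time series
    (nitrate, turbidity, dissolved oxygen, pH) using five sequential centered
    moving-window passes. Each pass computes masked rolling statistics (mean,
    median, or triangular-weighted mean) over the points not yet flagged and
    flags values falling outside dynamic bounds built from the rolling centre
    statistic, additive height constants, and a multiple of the rolling
    standard deviation, optionally gated by the manufacturer-stated sensor
    uncertainty. Wide windows stabilise the series against clusters of
    anomalous readings before narrow windows pick out single outliers.
    Includes readers and writers for delimited series and JSON
    parameterization files, a deterministic synthetic-fixture generator with
    ground-truth labelled global, local, and cluster anomalies, flag
    evaluation metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    ggplot2,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
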