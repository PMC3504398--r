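Package: dplsq
Title: Gene Regulatory Network Completion by Dynamic Programming and
    Least-Squares Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Completes or infers a directed gene regulatory network from
    gene-expression time series. Each gene's dynamics follow a discretized
    differential equation with linear and pairwise-product regulator terms;
    coefficients for any candidate regulator set are estimated by linear
    least squares, and a dynamic program distributes a fixed budget of edge
    deletions and additions across genes so that the total sum of squared
    errors is minimized. Includes a synthetic-data generator emulating the
    benchmark simulation protocol (uniform process and observation noise,
    multiple short series), edit-accuracy and success-rate evaluation, and
    TSV/SIF readers and writers for networks and series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
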