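Package: territr
Title: Territory Size Estimation from Intrusion Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures animal territory size from intrusion (playback)
    experiments. Provides a virtual-territory simulation framework, area and
    utilization-distribution estimators for the point patterns such experiments
    produce (minimum convex polygon, detailed/characteristic hull, fixed and
    adaptive bivariate normal kernels with reference or least-squares
    cross-validated bandwidths, k-LoCoH with automated minimum-spurious-hole
    selection of k), the "stretch-the-centre" estimator that rubbersheets
    central-kernel isoclines onto trial endpoints, and evaluation machinery
    (area-accumulation curves over equiangular trial subsets, rank-order
    stability, stepwise-change tables, isopleth coverage statistics) together
    with the 12-direction semi-random field trial scheduler and CSV/GeoJSON
    input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    withr
Config/testthat/edition: 3
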