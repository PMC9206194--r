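Package: txaccess
Title: Drive-Time Access to Confidential Family Planning Care for Minors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating how changes in the composition of a federally
    funded clinic network alter adolescents' access to confidential family
    planning services. Implements two-epoch clinic roster differencing with
    deduplication and affiliation classification, state minor
    consent/confidentiality law classification, road-network drive-time
    catchments around population-weighted census-tract centroids, a
    four-category tract-level access-change variable, youth-at-risk estimation
    stratified by Medicaid enrolment, univariate odds ratios with Wald
    confidence intervals, and segmented interrupted time series regression of
    annual clinic counts. A seed-reproducible synthetic geography generator
    with planted effect structure allows the whole pipeline to be exercised
    and validated without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    igraph,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
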