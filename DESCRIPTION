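Package: limnotraj
Title: Temporal Trajectories of Lake Microeukaryote Communities Along a
    Eutrophication Gradient
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing monthly 18S rRNA amplicon time series from
    lakes spanning a eutrophication gradient. Covers chlorophyll-a based
    Carlson trophic-state classification and campaign-level lake
    categorisation, trophic-mode annotation of amplicon sequence variants at
    the class rank, alpha diversity, Bray-Curtis ordination and PERMANOVA,
    multivariate trajectory analysis (cumulative path length of monthly
    community centroids through a shared principal-coordinate space),
    time-lag analysis with linear and polynomial model competition by AIC,
    SparCC compositional co-occurrence networks with trophic-mode module
    statistics, and a synthetic multi-lake community generator with known
    seasonal, gradient and drift structure for end-to-end validation.
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
    igraph,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
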