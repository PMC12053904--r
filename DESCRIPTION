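Package: spillwatch
Title: Disturbance Detection in Long-Term Marine Microbial Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream statistical analysis of multi-year coastal metagenome
    time series: RPKM feature-table normalization and taxonomic/functional
    aggregation, alpha diversity (Shannon, richness, Pielou), community
    structure (PCA on centered-scaled abundances, PERMANOVA, nearest-neighbor
    dissimilarity, complete-linkage clustering), indicator-feature analysis
    (IndVal with a permutation null), curated oil-responder panel tracking,
    and a seasonal-baseline anomaly detector that fits additive year + month
    linear models, partitions variability with Type II ANOVA, and flags
    post-disturbance samples whose residuals fall outside the empirical 95%
    interval of a decade of baseline residuals. A synthetic seasonal
    community simulator with injected pulse disturbances provides ground
    truth for calibration and testing.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
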