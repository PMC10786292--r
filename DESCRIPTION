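Package: connplast
Title: Longitudinal Structural Connectome Plasticity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal change in weighted structural
    brain networks, built around a bilateral language connectome with
    corpus-callosum waypoint regions. Provides connectome ingestion and
    group-level thresholding, hemispheric strength and lateralization
    summaries, edge-wise linear mixed-effects screening with participant
    random intercepts, permutation-based network-based statistics (NBS)
    with family-wise error control at the connected-component level,
    post-hoc period contrasts, behaviour-connectivity correlation
    subnetworks, and a synthetic longitudinal cohort generator for
    calibration and power studies.
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
    jsonlite,
    lme4,
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
    lmerTest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
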