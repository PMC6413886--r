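Package: synrescue
Title: Inference of Synthetic-Rescue Gene Interactions from Tumor and
    Cell-Line Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies synthetic-rescue (SR) gene pairs - pairs in which
    the fitness loss caused by inactivating a vulnerable gene is
    compensated by an activity change of a rescuer gene - by applying four
    sequential statistical screens to tumor molecular and clinical data
    and to cell-line perturbation screens: a conditional-essentiality
    mixed-model screen on shRNA/drug panels, a hypergeometric
    enrichment/depletion screen on tumor co-activity states, a stratified
    Cox proportional-hazards survival screen, and a phylogenetic-profile
    similarity filter based on non-negative matrix factorization.
    Downstream utilities score drug-tumor rescue burden, test
    Bliss-independence drug-combination synergy on sparse 1x5 dose
    designs, and benchmark predictions (precision/recall, ROC, Cohen's
    d). A synthetic-data generator plants SR structure in cohorts,
    screen panels, phylogenetic profiles, and dose grids so the whole
    pipeline is testable at desk scale.
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
    lme4,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
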