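Package: eyestrat
Title: Unsupervised Stratification of Item-Level Mentalizing Task Performance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Data-driven stratification of binary item-level task performance
    (such as the 36-item Reading the Mind in the Eyes Test) into replicable
    subgroups. Subjects are clustered on the topological overlap of their
    Hamming similarities with Ward linkage and a dynamic hybrid tree cut;
    subgroups are characterized with pairwise effect-size grids,
    item-difficulty profiles and FDR-controlled correlation grids; and
    subgroup labels are validated across independent cohorts with AdaBoost.M2
    multi-class classification and label-permutation testing. Includes a
    latent-class synthetic cohort generator so the full pipeline can be
    exercised without access to restricted clinical data.
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
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
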