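Package: metarescue
Title: Metabolomics-Guided Discovery of Drug Off-Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested workflow for locating the metabolic off-targets of an
    antibacterial compound from its systems-level footprint. Differential
    metabolomics (one-sided Mann-Whitney rank tests on log fold changes) feeds
    a multiclass mechanism-of-action classifier with leave-one-out evaluation
    and residual drug-specific signatures; constraint-based modelling of a
    folate-centric toy network scores candidate pathway inhibitions (flux caps,
    cofactor drains, knockouts) against experimental metabolite-supplementation
    growth-rescue patterns; binding-pocket Tanimoto fingerprints rank candidate
    proteins against a reference enzyme; and validation assays are quantified
    by logistic growth fits, four-parameter dose-response IC50 fits and
    Cheng-Prusoff inhibition constants. Seeded synthetic-data generators for
    every input make the whole pipeline reproducible offline.
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
    jsonlite,
    minpack.lm,
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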