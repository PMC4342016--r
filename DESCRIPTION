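Package: phylorao
Title: Taxonomic and Phylogenetic Diversity Partitioning Along Forest
    Modification Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rao quadratic-entropy partitioning of taxonomic and
    phylogenetic alpha- and beta-diversity for multi-group community
    surveys (e.g. successive plant life stages and birds), with
    tip-shuffle null models and standardized effect sizes, environmental
    gradient construction by correlation-matrix PCA with broken-stick
    retention, AICc model dredging and multimodel averaging of
    (mixed-effects) diversity regressions, partial Mantel tests, PCNM
    spatial eigenvector analysis with double-stop forward selection, and
    three-set variation partitioning of beta-diversity via distance-based
    redundancy analysis. Includes a synthetic-landscape generator that
    assembles communities under environmental filtering or limiting
    similarity along a disturbance gradient, so the whole pipeline can be
    exercised and calibrated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    igraph,
    knitr,
    rmarkdown,
    withr,
    jsonlite,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
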