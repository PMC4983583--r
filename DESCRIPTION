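Package: traitassembly
Title: Trait-Based Community Assembly Along Environmental Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing inter- and intraspecific variation in leaf
    mass per area (LMA) along environmental gradients in light of community
    assembly. Implements leaf-to-tree trait aggregation with petiole-mass
    correction and variance-based outlier filtering, community-weighted means
    and variances with sampling-bias normalisation, T-statistic variance
    ratios (within-population vs within-community, community vs regional pool)
    with permutation null models and standardized effect sizes, nested
    random-effects variance components, the decomposition of community-weighted
    mean variation into species-turnover, intraspecific and covariance parts,
    and Sorensen/Mantel beta-diversity analysis. Ships a synthetic-community
    generator with known hierarchical variance structure and filter strengths
    so every stage of the pipeline can be validated against a recoverable
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nlme,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    tidyr,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
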