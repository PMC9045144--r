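Package: cstnet
Title: Community State Types and Co-Occurrence Networks for Microbiome
    Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Discovers recurrent compositional patterns (community state
    types) in species-level microbiome relative-abundance tables by
    hierarchical clustering with silhouette-guided model selection, flags
    high prevalence clusters, ranks the driver taxa that define them by
    variance explained, and builds signed, significance-filtered
    co-occurrence networks from rank correlations with modularity-based
    community detection.  Includes alpha/beta diversity summaries
    (threshold species richness, Bray-Curtis, principal coordinates
    analysis, PERMANOVA) and a seeded synthetic-cohort generator that
    plants community states, group associations, driver taxa and
    taxon-taxon correlations so every stage of the pipeline can be
    validated against known truth.
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
    ape,
    cluster,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
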