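Package: discordia
Title: Gene Tree Discordance Profiling Against Coalescent Expectations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies gene-tree/species-tree discordance in multilocus
    phylogenomic datasets and tests whether the observed discordance is
    explicable by incomplete lineage sorting alone. Provides normalized
    Robinson-Foulds, Nye, and clustering-information tree distances with
    exact optimal split matching, a contained-coalescent simulator of gene
    trees within a species tree (optionally with reticulation events under
    an inheritance probability), Phyparts-style per-clade concordance
    tallies, normalized quartet scores, and the observed-versus-expected
    statistical layer (Welch t-tests, one-way ANOVA, Tukey-Kramer post hoc
    comparisons with compact letter displays). A synthetic-study generator
    emulates anchored-enrichment-style datasets (taxon dropout, gene-tree
    estimation error, bootstrap-like supports) so the full pipeline is
    testable without sequence data.
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
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
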