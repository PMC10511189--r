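Package: pdoption
Title: Phylogenetic Diversity Maximization and the Option Value of Biodiversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to test whether selecting species to maximize Faith's
    phylogenetic diversity (PD) captures species with known human uses better
    than random or extinction-risk-based selection. Implements rooted Faith
    PD, fair-proportion evolutionary distinctiveness (ED) and EDGE scores,
    exact greedy PD-maximizing set selection over tree ensembles
    (optionally on top of a secured low-risk baseline), tip-shuffle
    dispersion null models with standardized effect sizes, weighted and
    Red-List-controlled sampling without replacement, taxonomic
    overrepresentation permutation tests, top-set overlap of
    distinctiveness measures, and a seeded synthetic-data generator (Yule
    tree ensembles plus species attribute tables with controllable use
    prevalence, phylogenetic clumping, Red List composition and ED-FDist
    correlation) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
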