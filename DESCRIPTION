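Package: treeclone
Title: Morphological Tree Clones from Quantitative Structure Models
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a stochastic, self-organizing tree growth simulator to a
    target tree given as a cylinder table (a quantitative structure model,
    QSM) and generates "morphological clones": stochastic trees that share
    the target's coarse architecture while varying in fine-scale branching.
    Structural similarity between trees is measured by a projection
    (tomography) distance: empirical branch- and segment-feature tables are
    projected onto quasi-random line directions and compared with the
    two-sample Kolmogorov-Smirnov statistic, averaged over lines. A
    mixed-integer genetic algorithm minimises this distance over the
    simulator parameters. Includes cylinder-table I/O, Gravelius order
    assignment, classical allometric metrics (height, girth, crown spread),
    and synthetic QSM-like target generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
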