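Package: morphoscreen
Title: Co-Expression Screening, Pellet Morphometry and Fermentation
    Statistics for Filamentous Fungi
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying candidate genes transcriptionally coupled
    to multiple cellular processes in filamentous fungi, and for quantifying
    the phenotypes of the resulting mutants. Builds Spearman rank
    co-expression networks from a genes-by-conditions expression compendium,
    runs multi-query subnetwork intersection screens, and characterises
    candidate lists by hypergeometric GO-term over-representation with
    Benjamini-Hochberg false-discovery-rate control. Quantifies submerged
    culture macromorphology from binary images: 8-connected structure
    labelling, Feret diameters by rotating calipers on pixel-corner convex
    hulls, solidity, pellet versus dispersed classification by area, and the
    dimensionless Morphology Number. Normalises fermentation titres to
    biomass or depleted glucose, compares mutants to a progenitor control by
    pairwise Student's t-tests, and fits polynomial trend curves between
    product titres. Seeded synthetic-data generators for expression
    matrices with planted co-expression modules, binary culture images with
    known shape ground truth, and dose-response fermentation tables make
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    igraph,
    png,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
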