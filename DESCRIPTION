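Package: vesselyeast
Title: Analysis Toolkit for Yeasts Isolated from Ancient Fermentation Vessels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the computational chain used to characterise yeast
    strains isolated from ancient beverage vessels: patristic-distance species
    delimitation on barcode trees, Robinson-Foulds intertree distances with
    density-based tree clustering, multiple-sequence-alignment curation
    (centroid dereplication, gap trimming, parsimony-informative filtering,
    ortholog occupancy), gene copy-number signature scoring, logistic
    growth-curve fingerprinting with PCA classification, exact
    isolation-frequency enrichment testing, and beverage chemistry and flavor
    profiling (GC-MS peak normalisation, Ward clustering with bootstrap node
    support, beer colour scales, carbohydrate quantitation, taste-sheet
    aggregation). A seeded synthetic-data module emulates every input with
    planted ground truth so each stage has a parameter-recovery test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    MASS,
    minpack.lm,
    stats,
    utils
Suggests:
    phangorn,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
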