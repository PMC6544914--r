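Package: ghstox
Title: Harmonizing GHS Acute Toxicity Annotations and Heterogeneous
    Descriptor Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pooling Globally Harmonized System (GHS) acute
    toxicity classifications from multiple regulatory sources into a single
    harmonized per-route label, standardizing and deduplicating chemical
    structures, assembling molecular, protein-target and quantitative
    high-throughput screening (qHTS) descriptor blocks, screening for
    toxicophores with enrichment statistics, quantifying class separation
    (nearest-neighbour distance distributions and a regularized linear
    discriminant), and training and evaluating Random Forest acute oral
    toxicity classifiers over random, rare-scaffold and single-source
    train/test splits. A synthetic study generator with a known generative
    model provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
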