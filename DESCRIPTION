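Package: nomtrait
Title: Functional Groups from Nominal Trait Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for deriving and validating functional groups of species
    from categorical (nominal) trait matrices. Provides readers and
    validators for species-by-trait data with codebooks, discretization of
    continuous traits, mode and polytomous chained-equations imputation with
    an accuracy-benchmark simulation, five categorical dissimilarity
    measures (simple matching, Eskin, IOF, Goodall, Lin), agglomerative
    hierarchical clustering with single, complete and average linkage,
    partitioning around medoids, entropy- and Gini-based internal validity
    indices (within-cluster entropy coefficient and entropy pseudo-F),
    bootstrap Jaccard cluster stability, the adjusted Rand index, a seeded
    synthetic-data generator with planted group structure, and a one-call
    analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
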