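Package: moclust
Title: Knowledge-Guided Multi-Objective Clustering of Gene Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-objective evolutionary clustering of genes that
    simultaneously optimises an expression-based and a Gene Ontology
    knowledge-based version of a medoid cluster validity index (Xie-Beni,
    overall deviation or separation) with an NSGA-II engine augmented by
    multi-objective path-relinking (intensification) and Pareto local
    search (diversification). Includes Wang semantic similarity over OBO
    ontologies, Pearson-correlation expression distances, 2-D hypervolume
    and silhouette-based solution selection, a tie-corrected Friedman
    comparison test, hypergeometric term-enrichment p-values, and a seeded
    synthetic-data generator with planted co-expressed, co-annotated gene
    clusters for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), mclust, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
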