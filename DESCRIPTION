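Package: idconv
Title: Phenotype Convergence Analysis for Heterogeneous Intellectual
    Disability Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis of genotype-phenotype convergence in systematically
    phenotyped intellectual-disability cohorts.  Provides per-gene
    hypergeometric enrichment of phenotypes and of co-occurring phenotype
    pairs, construction and topological classification (radial / dense /
    mixed) of phenotype co-occurrence networks, patient phenotype-similarity
    analyses (intra- versus inter-gene and within-family comparisons),
    fuzzy matching of free-text phenotype descriptions to a standard
    vocabulary, enrichment-based candidate-gene ranking with an evaluation
    harness, and an SVM-based pathogenicity predictor.  A synthetic-cohort
    generator with planted gene-phenotype structure supplies recoverable
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    e1071,
    igraph,
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
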