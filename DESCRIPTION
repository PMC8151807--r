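Package: calfgrow
Title: Genetic Evaluation and Genome-Wide Association for Yearling
    Weight Gain in Dairy Calves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative-genetic analysis of yearling
    weight gain in dairy calves: trait construction from repeated field
    weighings, data editing, pedigree algebra (inbreeding, inverse
    numerator relationship matrix, unknown-parent genetic groups),
    a repeatability animal model with sex-heterogeneous variances solved
    by sparse mixed-model equations, EM/AI-REML variance components,
    genetic and phenotypic trend estimation, single-marker association of
    sire transmitting abilities with max-statistic permutation control of
    the family-wise error rate, and GRM-based REML (GREML) estimation of
    the SNP-captured fraction of variance. Includes a simulator that
    generates pedigrees, weight records and genotypes with known truth
    for validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
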