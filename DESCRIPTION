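Package: iguanachem
Title: Chemical Signature Analysis of Land Iguana Femoral Gland Secretions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for GC-MS compound relative-abundance profiles
    of femoral gland secretions from two syntopic Galapagos land iguana
    species (Conolophus marthae and C. subcristatus). Implements per-sample
    chemical diversity and group richness summaries, Bray-Curtis
    dissimilarity, principal coordinates analysis and non-metric
    multidimensional scaling, PERMDISP-style multivariate dispersion
    homogeneity tests with Tukey HSD screening, sequential sum-of-squares
    PERMANOVA with strata-restricted permutations, SIMPER decomposition with
    permutation significance and Bonferroni correction, PCA-based marker
    reduction, and a repeated stratified random-forest importance-stability
    protocol with chi-squared uniformity testing, averaged classification
    metrics, and pooled ROC/AUC. Includes a synthetic compound-table
    generator emulating the study design (sparse compositional profiles with
    planted species, sex and year effects) so every stage is testable
    without the field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ape,
    jsonlite
Config/testthat/edition: 3
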