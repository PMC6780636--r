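Package: micromet
Title: Multi-Group Classification and Cross-Correlation of Paired
    Microbiome and Metabolome Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrated analysis of paired gut-microbiome (genus-level
    relative abundance) and plasma-metabolome (peak area) tables across
    several clinical groups. Implements repeated nested cross-validation
    with stochastic hill-climbing feature selection over a fixed zoo of
    classifiers scored by weighted one-vs-one balanced accuracy;
    confounder-adjusted partial cross-correlation of genera against
    metabolites with Westfall-Young min-p permutation correction and
    Ward bi-clustering into centroid-aggregated simplified matrices;
    alpha-diversity indices with rarefaction curves; Kruskal-Wallis/Dunn
    univariate screening; and a FreeViz-style radial projection. A
    synthetic cohort generator with planted group effects and
    genus-metabolite correlation blocks makes every stage testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    e1071,
    ranger,
    vegan,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
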