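Package: methrepro
Title: Reproducibility of Differential DNA Methylation and Its Concordance
    with Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing batch effects in array-based DNA
    methylation data (per-probe one-way ANOVA, hierarchical-clustering
    batch purity), calling differentially methylated and differentially
    expressed genes (paired/Welch t-tests with Benjamini-Hochberg control,
    and a permutation-based SAM statistic), scoring cross-dataset
    reproducibility of gene lists (percentage of overlapping genes,
    direction consistency under an exact binomial null), quantifying
    concordance between promoter methylation change and expression change
    with hypergeometric tests, and hypergeometric gene-set
    over-representation against GMT collections.  A synthetic-cohort
    generator produces paired tumour/normal methylation and expression
    datasets with known batch structure, differential signal and
    methylation-expression coupling for validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mclust
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
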