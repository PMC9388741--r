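Package: marrowmir
Title: Marrow Adiposity Quantification and miRNA Screening After Spinal Cord Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the link between circulating microRNAs and
    bone-marrow adipose tissue after spinal cord injury. Implements
    calibrated quantitative-CT quantification of marrow adipose tissue
    volume and trabecular bone mineral content from knee scans,
    median-of-ratios library-size normalization and differential screening
    of small-RNA count matrices, secondary-structure criteria filtering of
    novel pre-miRNA hairpin candidates, summary-statistic cohort tests
    (pooled and Satterthwaite t, one-way ANOVA, Tukey-Kramer, Fisher exact,
    Pearson chi-squared), univariate and multivariable linear association
    models with a p-value inclusion rule, and consensus target prediction.
    Seeded synthetic-data generators (cohort tables, negative-binomial
    counts, CT phantoms with known ground truth, hairpin candidates) make
    every stage testable without access to subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
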