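Package: aromascreen
Title: Differential Volatile-Compound and Aroma-Activity Analysis for GC-MS Peak Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for two-group differential analysis of
    volatile compounds measured by headspace GC-MS: Kovats retention-index
    assignment from an n-alkane ladder, library-match filtering, relative
    quantification of peak areas, chemometric screening (Z-scoring,
    hierarchical clustering, PCA, OPLS-DA with cross-validated Q2,
    permutation validation and VIP scores, two-sample t-tests), selection of
    key compounds by VIP > 1 and p < 0.05, relative odor activity values
    (rOAV) with reference-compound normalisation, and aroma-type profiling
    from odor descriptors. Includes a synthetic-data generator with known
    ground truth and a built-in reference dataset of volatile compounds in
    young and mature Docynia delavayi fruit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
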