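Package: jointgp
Title: Joint-Population Genomic Prediction of Ordinal Hip Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic prediction of ordinal hip-dysplasia scores
    (Norberg-angle scores) across two diverged dog populations. Simulates
    two-population cohorts with a polygenic ordinal trait, builds VanRaden
    genomic relationship matrices, estimates variance components by
    average-information REML, predicts genomic breeding values under joint,
    single-population and balanced cross-validation training designs,
    preselects SNPs by linear mixed-model GWAS, and quantifies genome
    coverage of SNP subsets via haplotype blocks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
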