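Package: gvdtest
Title: Kernel Association Statistics by Genotype Value Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the per-site quadratic-form statistics used by
    sequence kernel association tests (SKAT) - the genetic relationship
    matrix (GRM) statistic and the identity-by-state (IBS) statistic -
    in O(n) time per site from genotype indicator vectors, without ever
    constructing an n-by-n kernel matrix. Includes a brute-force matrix
    oracle for verification, a seedable permutation-test engine for
    p-values, a Hardy-Weinberg genotype and carrier-shift phenotype
    simulator for power studies, and readers and writers for VCF
    genotypes, phenotype tables and result files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
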