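Package: mmragwas
Title: Mixed-Model Single-Locus GWAS with Permutation Thresholds and LD-Block QTL Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A family-based genome-wide association pipeline for pedigreed
    populations: builds the pedigree additive relationship matrix, estimates
    additive and residual variance components of an animal model by restricted
    maximum likelihood, scans SNPs one at a time with a mixed-model Wald
    chi-squared test (variance components fixed across the scan), sets the
    genome-wide significance threshold from the permutation distribution of the
    maximum statistic, and delimits QTL regions as D-prime linkage
    disequilibrium blocks under the Gabriel confidence-interval criteria.
    Includes a gene-dropping simulator of a two-generation half-sib design
    (sires by dams by progeny, mosaic founder haplotypes, additive, imprinted
    and epistatic trait loci) so the whole pipeline can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
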