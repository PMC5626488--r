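Package: gwherit
Title: GREML Heritability and Genetic-Architecture Analysis for
    Case-Control Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates SNP heritability of binary (case-control) traits by
    restricted maximum likelihood on genetic relatedness matrices (GREML),
    converts estimates to the liability scale with correction for
    case-control ascertainment, and partitions heritability by chromosome,
    minor-allele-frequency bin, genic annotation and cis-eQTL status.
    Includes covariate-adjusted logistic-regression association scans with
    an ordinal skin-color covariate, permutation tests for subset
    heritability and for eQTL enrichment among top association signals,
    genotype and sample quality control, PLINK and GCTA-dialect binary
    readers and writers, and a synthetic-cohort generator with a
    liability-threshold disease model and known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
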