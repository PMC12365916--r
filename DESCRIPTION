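Package: dohaplo
Title: Benchmarking Founder Haplotype Reconstruction from Low-Coverage
    Sequencing in Diversity Outbred Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates Diversity Outbred (DO) mouse cohorts with known founder
    mosaics and benchmarks haplotype reconstruction from low-coverage
    sequencing against array-style genotyping. Provides a 36-state founder
    diplotype hidden Markov model for genotype imputation and haplotype
    reconstruction, IMPUTE-style INFO scores with adaptive marker filtering,
    identity-by-descent segment detection among the eight inbred founders,
    cosine-similarity concordance between reconstructions with discordant
    region classification, crossover counting, and an expression QTL scan with
    founder allele-effect estimation for comparing genotyping methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
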