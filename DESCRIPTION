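Package: twasim
Title: Simulation and Power Analysis for Transcriptome-Wide Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates transcriptome-wide association study (TWAS) test
    statistics at a cis locus under configurable genetic architectures.
    Reads PLINK genotype reference panels, estimates and regularizes
    linkage-disequilibrium (LD) matrices, samples sparse eQTL effect
    vectors at a target cis-heritability, simulates GWAS summary
    statistics either from individual-level genotypes (standard mode) or
    directly from an LD-parameterized multivariate normal (fast mode),
    fits expression prediction models (LASSO, elastic net, GBLUP, true
    effects, or user-supplied plugins), computes gene-level TWAS
    statistics under matched or misspecified LD references, and evaluates
    calibration (Kolmogorov-Smirnov normality, genomic inflation,
    family-wise error rate) and statistical power across replicate
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
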