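Package: gbselect
Title: Simulating Genotyping-by-Sequencing and SNP Arrays for Genomic Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for comparing low-coverage genotyping-by-sequencing
    (GBS) with SNP-array genotyping in livestock genomic selection. Generates base
    haplotype panels with a realistic allele-frequency spectrum and linkage
    disequilibrium (or imports ms/MaCS-style coalescent output), gene-drops a
    two-generation sire-dam pedigree, simulates a polygenic trait, calls genotypes
    from Poisson-distributed read depths with mean-dosage filling of missing calls,
    fits the ridge-regression (SNP-BLUP) prediction model with known variance
    components, and evaluates prediction accuracy, bias, and response to selection
    under fixed total sequencing budgets spread over variable numbers of
    individuals.
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
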