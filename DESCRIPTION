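Package: herdchar
Title: SNP-Chip Characterization of Structured Livestock Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for characterizing labelled diploid populations from
    biallelic SNP-array genotypes: PLINK text/binary input and output,
    call-rate quality control and windowed LD pruning, within-population
    diversity summaries (MAF, observed and unbiased expected
    heterozygosity, inbreeding coefficient), Weir-Cockerham F-statistics
    with locus bootstrap and permutation tests, three-level analysis of
    molecular variance, Nei's D_A distances with neighbor-joining trees
    and bootstrap supports, allele-frequency PCA, model-based admixture
    estimation by EM with cross-validation over masked genotype entries,
    binned linkage-disequilibrium decay, and LD-based historical
    effective population size.  Includes seeded genotype simulators
    (Balding-Nichols, forward Wright-Fisher with recombination, known
    admixture, inbreeding injection) so every estimator is validated by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
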