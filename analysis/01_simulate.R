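#!/usr/bin/env Rscript
# Build the synthetic study cohort: five breeds at unequal sample sizes and
# differentiation levels (Balding-Nichols), with mild inbreeding injected
# into one breed so every downstream estimator has a known truth to recover.
# Writes PLINK binary files under results/data/.

library(herdchar)

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

set.seed(42)
ds <- simulate_balding_nichols(
  n_pops = 5, n_per_pop = c(40, 30, 25, 15, 10), n_loci = 4000,
  fst = c(0.05, 0.05, 0.10, 0.20, 0.30), seed = 42
)
# spread the panel over a 40 Mb chromosome so LD analyses have distances
ds$snps$pos <- as.integer(seq_len(n_snps(ds)) * 10000L)
# breed 2 carries inbreeding at F = 0.10
rows <- ds$samples$population == "pop2"
inb <- inject_inbreeding(subset_dataset(ds, samples = which(rows)), 0.10, seed = 43)
ds$genotypes[rows, ] <- inb$genotypes

write_genotypes(ds, "results/data/cohort", "plink-binary")
cat(sprintf("cohort: %d animals x %d SNPs, %d breeds; truth: F per breed = (0.05, 0.05, 0.10, 0.20, 0.30), breed pop2 inbred at F_IS = 0.10\n",
            n_samples(ds), n_snps(ds), length(populations(ds))))
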