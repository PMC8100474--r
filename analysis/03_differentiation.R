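#!/usr/bin/env Rscript
# Population differentiation: global Weir-Cockerham F-statistics with
# bootstrap CIs and permutation tests, the pairwise F_ST matrix, and the
# three-level AMOVA.  The among-population AMOVA percentage should agree
# with 100 * F_ST.

library(herdchar)

ds <- read_genotypes("results/data/cohort", "plink-binary")

fs <- global_fstats(ds, n_boot = 1000, n_perm = 199, seed = 1)
print(fs)
jsonlite::write_json(
  list(fst = fs$fst, fis = fs$fis, fit = fs$fit,
       fit_from_identity = wright_identity(fs$fis, fs$fst),
       p_value = as.list(fs$p_value)),
  "results/fstats.json", auto_unbox = TRUE, pretty = TRUE, digits = NA)

pw <- pairwise_fst(ds)
write.table(round(pw, 4), "results/pairwise_fst.tsv", sep = "\t", quote = FALSE)
cat("pairwise F_ST range:", round(min(pw[upper.tri(pw)]), 3), "-",
    round(max(pw[upper.tri(pw)]), 3), "\n")

am <- amova_three_level(ds, n_perm = 199, seed = 2)
print(am)
tab <- data.frame(level = names(am$sigma2), df = am$df, SS = am$SS,
                  sigma2 = am$sigma2, percent = am$percents, p = am$p_values)
write.table(tab, "results/amova.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("finding: AMOVA among-breed %.1f%% vs 100*F_ST = %.1f\n",
            am$percents[["among_pops"]], 100 * fs$fst))
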