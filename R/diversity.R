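#' Per-population allele frequency
#'
#' Frequency of the globally-oriented counted allele at every SNP within one
#' population, using non-missing calls only.  SNPs with no calls in the
#' population are returned as `NA` (undefined).
#'
#' @param ds a [genotype_dataset()].
#' @param population population label.
#' @return numeric vector, one frequency per SNP.
#' @export
pop_allele_freq <- function(ds, population) {
  validate_genotype_dataset(ds)
  sub <- ds$genotypes[pop_rows(ds, population), , drop = FALSE]
  n <- colSums(!is.na(sub))
  ifelse(n > 0, colSums(sub, na.rm = TRUE) / (2 * n), NA_real_)
}

#' Within-population diversity summaries
#'
#' For every population with at least two samples: per-SNP observed
#' heterozygosity (fraction heterozygous among non-missing calls), expected
#' heterozygosity, minor allele frequency, and the inbreeding coefficient
#' F_IS.  Means and SDs are taken across SNPs; SNPs monomorphic within the
#' population contribute H_O = H_E = 0 (genome-wide-mean semantics), while
#' SNPs with no calls are excluded.
#'
#' H_E uses the unbiased small-sample form (2n/(2n-1)) 2p(1-p) by default
#' (`unbiased_he = FALSE` gives plain 2p(1-p)).  F_IS is the Weir-Cockerham
#' within-population f (ratio of summed b and c components over loci), which
#' can be negative under heterozygote excess; the simple moment form
#' 1 - mean(H_O)/mean(H_E) is reported alongside as `fis_simple`.
#'
#' @param ds a [genotype_dataset()].
#' @param unbiased_he use the Nei (1978)-style small-sample correction.
#' @return data.frame with one row per population: `population`, `n`,
#'   `maf_mean`, `maf_sd`, `ho_mean`, `ho_sd`, `he_mean`, `he_sd`, `fis`,
#'   `fis_simple`, `n_snps_used`.
#' @export
diversity_summary <- function(ds, unbiased_he = TRUE) {
  validate_genotype_dataset(ds)
  pops <- populations(ds)
  sizes <- table(ds$samples$population)[pops]
  if (any(sizes < 2)) {
    warning("excluding population(s) of size 1: ",
            paste(pops[sizes < 2], collapse = ", "))
    pops <- pops[sizes >= 2]
  }
  if (length(pops) == 0) stop("no population with >= 2 samples")
  rows <- lapply(pops, function(popname) {
    sub <- ds$genotypes[pop_rows(ds, popname), , drop = FALSE]
    n <- colSums(!is.na(sub))
    ok <- n > 0
    nn <- n[ok]
    p <- colSums(sub[, ok, drop = FALSE], na.rm = TRUE) / (2 * nn)
    ho <- colMeans(sub[, ok, drop = FALSE] == 1L, na.rm = TRUE)
    he <- 2 * p * (1 - p)
    if (unbiased_he) he <- he * (2 * nn) / (2 * nn - 1)
    maf <- pmin(p, 1 - p)
    bc <- wc_single_pop_bc(nn, p, ho)
    denom <- sum(bc$b) + sum(bc$c)
    fis <- if (denom > 0) 1 - sum(bc$c) / denom else 0
    fis_simple <- if (mean(he) > 0) 1 - mean(ho) / mean(he) else 0
    data.frame(population = popname, n = nrow(sub),
               maf_mean = mean(maf), maf_sd = stats::sd(maf),
               ho_mean = mean(ho), ho_sd = stats::sd(ho),
               he_mean = mean(he), he_sd = stats::sd(he),
               fis = fis, fis_simple = fis_simple,
               n_snps_used = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
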