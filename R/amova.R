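#' Three-level analysis of molecular variance
#'
#' Treats each diploid as two allele copies per locus (gametic coding,
#' phase-free) with the simple mismatch distance, and partitions the total
#' allelic variance into among-population, among-individual-within-population
#' and within-individual components by the standard hierarchical
#' sums-of-squares / expected-mean-square equations, with sums of squares
#' and degrees of freedom accumulated over loci (complete-case per locus).
#' Intermediate components can be negative and are reported as computed.
#'
#' Permutation significance: whole individuals are shuffled across
#' populations for the among-population component (p = fraction of
#' permuted components >= observed); allele copies are re-paired at random
#' within populations for the two lower levels (among-individual p is
#' upper-tail, within-individual p is lower-tail, since inbreeding inflates
#' the former and depresses the latter).
#'
#' @param ds a [genotype_dataset()] with >= 2 populations of >= 2 samples.
#' @param n_perm permutation replicates (0 = no p-values).
#' @param seed integer RNG seed for the permutations.
#' @return an `amova_result` list: `sigma2` (named length-3 vector),
#'   `percents` (summing to 100 exactly), `df`, `SS`, optional `p_values`,
#'   `n_perm`, `seed`.
#' @export
amova_three_level <- function(ds, n_perm = 0, seed = 1) {
  validate_genotype_dataset(ds)
  pops <- populations(ds)
  if (length(pops) < 2) stop("need >= 2 populations")
  if (any(table(ds$samples$population) < 2))
    stop("every population needs >= 2 individuals")
  st <- pop_locus_stats(ds)
  obs <- amova_components(st$n, st$p, st$h)
  res <- structure(list(
    sigma2 = obs$sigma2, percents = 100 * obs$sigma2 / sum(obs$sigma2),
    df = obs$df, SS = obs$SS, n_perm = n_perm, seed = seed
  ), class = "amova_result")
  if (n_perm > 0) {
    set.seed(seed)
    hits <- c(0, 0, 0)
    perm_ds <- ds
    for (i in seq_len(n_perm)) {
      # among-population level: individuals shuffled across populations
      perm_ds$samples$population <- sample(ds$samples$population)
      stp <- pop_locus_stats(perm_ds)
      pa <- amova_components(stp$n, stp$p, stp$h)$sigma2[1]
      if (pa >= obs$sigma2[1]) hits[1] <- hits[1] + 1
      # lower levels: allele copies re-paired within populations
      h_perm <- st$h
      for (k in seq_len(ncol(st$n)))
        h_perm[, k] <- random_pairing_het(st$n[, k],
                                          round(2 * st$n[, k] * st$p[, k]))
      pl <- amova_components(st$n, st$p, h_perm)$sigma2
      if (pl[2] >= obs$sigma2[2]) hits[2] <- hits[2] + 1
      if (pl[3] <= obs$sigma2[3]) hits[3] <- hits[3] + 1
    }
    res$p_values <- stats::setNames((hits + 1) / (n_perm + 1), names(obs$sigma2))
  }
  res
}

# hierarchical SS -> variance components from per-locus (n, p, h) matrices
amova_components <- function(n, p, h) {
  p[n == 0] <- 0; h[n == 0] <- 0
  P_l <- rowSums(n > 0)
  use <- P_l >= 2
  n <- n[use, , drop = FALSE]; p <- p[use, , drop = FALSE]
  h <- h[use, , drop = FALSE]; P_l <- P_l[use]
  N_l <- rowSums(n)
  pbar <- rowSums(n * p) / N_l
  # genotype-class counts per population from (n, p, h)
  n1 <- n * h                  # heterozygotes
  n2 <- n * (p - h / 2)        # counted-allele homozygotes
  n0 <- n - n1 - n2
  SS_c <- 0.5 * rowSums(n1)
  SS_b <- 2 * rowSums(n2 * (1 - p)^2 + n1 * (0.5 - p)^2 + n0 * p^2)
  SS_a <- 2 * rowSums(n * (p - pbar)^2)
  df_a <- P_l - 1
  df_b <- N_l - P_l
  df_c <- N_l
  nc_l <- (2 * N_l - rowSums((2 * n)^2) / (2 * N_l)) / df_a
  SS <- c(among_pops = sum(SS_a), among_ind_within = sum(SS_b),
          within_ind = sum(SS_c))
  df <- c(among_pops = sum(df_a), among_ind_within = sum(df_b),
          within_ind = sum(df_c))
  nc <- sum(nc_l * df_a) / sum(df_a)  # df-weighted; exact for complete data
  ms <- SS / df
  s2_c <- ms[["within_ind"]]
  s2_b <- (ms[["among_ind_within"]] - s2_c) / 2
  s2_a <- (ms[["among_pops"]] - s2_c - 2 * s2_b) / nc
  list(sigma2 = c(among_pops = s2_a, among_ind_within = s2_b,
                  within_ind = s2_c),
       SS = SS, df = df)
}

#' @export
print.amova_result <- function(x, ...) {
  tab <- data.frame(df = x$df, SS = round(x$SS, 3),
                    sigma2 = round(x$sigma2, 5),
                    percent = round(x$percents, 2))
  if (!is.null(x$p_values)) tab$p <- signif(x$p_values, 3)
  cat("AMOVA (allele-copy coding, summed over loci)\n")
  print(tab)
  invisible(x)
}
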