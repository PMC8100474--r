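# Independent brute-force oracles, deliberately written with explicit loops
# and first-principles formulas so they share no code path with the package.

# hand-build a dataset from a dosage matrix and population labels
make_ds <- function(g, pops, pos = NULL, chrom = NULL) {
  g <- as.matrix(g)
  m <- ncol(g)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(chrom)) chrom <- rep(1L, m)
  genotype_dataset(
    g,
    snps = data.frame(id = sprintf("s%d", seq_len(m)), chrom = chrom,
                      pos = as.integer(pos), allele_a = rep("A", m),
                      allele_b = rep("B", m)),
    samples = data.frame(id = sprintf("i%d", seq_len(nrow(g))), population = pops)
  )
}

# nested ANOVA on allele copies at one locus: explicit sums of squares over
# (population / individual / copy), returning mean squares and the
# method-of-moments variance components.  Heterozygote copies are (0, 1);
# phase does not matter for sums of squares.
anova_alleles_oracle <- function(genos, pops) {
  keep <- !is.na(genos)
  genos <- genos[keep]; pops <- pops[keep]
  copies <- list()
  for (i in seq_along(genos)) {
    g <- genos[i]
    copies[[i]] <- if (g == 1) c(0, 1) else c(g / 2, g / 2)
  }
  N <- length(genos)
  upops <- unique(pops)
  r <- length(upops)
  grand <- mean(unlist(copies))
  ss_a <- ss_b <- ss_c <- 0
  for (pp in upops) {
    idx <- which(pops == pp)
    pop_vals <- unlist(copies[idx])
    pop_mean <- mean(pop_vals)
    ss_a <- ss_a + length(pop_vals) * (pop_mean - grand)^2
    for (i in idx) {
      ind_mean <- mean(copies[[i]])
      ss_b <- ss_b + 2 * (ind_mean - pop_mean)^2
      ss_c <- ss_c + sum((copies[[i]] - ind_mean)^2)
    }
  }
  n_p <- sapply(upops, function(pp) sum(pops == pp))
  ms_a <- ss_a / (r - 1)
  ms_b <- ss_b / (N - r)
  ms_c <- ss_c / N
  nc2 <- (2 * N - sum((2 * n_p)^2) / (2 * N)) / (r - 1)  # copies scale
  sigma_c <- ms_c
  sigma_b <- (ms_b - ms_c) / 2
  sigma_a <- (ms_a - ms_b) / nc2
  list(SS = c(ss_a, ss_b, ss_c), df = c(r - 1, N - r, N),
       sigma2 = c(sigma_a, sigma_b, sigma_c))
}

# exhaustive greedy windowed pruning, with r^2 computed from the raw
# covariance definition on pairwise-complete cases
prune_oracle <- function(g, chroms, pos, window, step, thr) {
  r2_pair <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    va <- sum((a - mean(a))^2); vb <- sum((b - mean(b))^2)
    if (va == 0 || vb == 0) return(0)
    (sum((a - mean(a)) * (b - mean(b))))^2 / (va * vb)
  }
  maf <- apply(g, 2, function(x) {
    p <- mean(x, na.rm = TRUE) / 2; min(p, 1 - p)
  })
  keep <- rep(TRUE, ncol(g))
  for (chr in unique(chroms)) {
    idx <- which(chroms == chr)
    start <- 1
    repeat {
      win <- idx[start:min(start + window - 1, length(idx))]
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2) break
        worst <- 0; wi <- wj <- NA
        for (x in seq_along(act)) for (y in seq_along(act)) {
          if (x >= y) next
          r2 <- r2_pair(g[, act[x]], g[, act[y]])
          if (r2 > worst) { worst <- r2; wi <- act[x]; wj <- act[y] }
        }
        if (worst <= thr) break
        drop <- if (maf[wi] < maf[wj]) wi
        else if (maf[wj] < maf[wi]) wj
        else if (pos[wi] > pos[wj]) wi else wj
        keep[drop] <- FALSE
      }
      if (start + window - 1 >= length(idx)) break
      start <- start + step
    }
  }
  which(keep)
}

# random additive tree: random topology with positive branch lengths,
# returning the tree and its exact path-length distance matrix
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(n) stats::runif(n, 0.1, 1))
  list(tree = tr, d = cophenetic(tr))
}
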