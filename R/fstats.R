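#' Weir-Cockerham variance components at one locus
#'
#' Computes the among-population (a), among-individual-within-population (b)
#' and within-individual (c) variance components of the 1984
#' method-of-moments estimator from per-population sample sizes, counted
#' allele frequencies and heterozygote frequencies.  A locus monomorphic
#' across all populations yields (0, 0, 0) and is flagged uninformative.
#'
#' @param n per-population counts of genotyped individuals (length >= 2).
#' @param p per-population counted-allele frequencies.
#' @param h per-population heterozygote fractions.
#' @return list with `a`, `b`, `c` and logical `informative`.
#' @export
wc_locus_components <- function(n, p, h) {
  keep <- n > 0
  n <- n[keep]; p <- p[keep]; h <- h[keep]
  r <- length(n)
  if (r < 2) stop("need >= 2 populations with data at the locus")
  comp <- wc_components_matrix(matrix(n, 1), matrix(p, 1), matrix(h, 1))
  list(a = comp$a[1], b = comp$b[1], c = comp$c[1],
       informative = comp$a[1] + comp$b[1] + comp$c[1] > 0)
}

# vectorised over loci: n, p, h are loci x populations matrices
# (n = 0 marks a population with no data at that locus)
wc_components_matrix <- function(n, p, h) {
  r_eff <- rowSums(n > 0)
  p[n == 0] <- 0; h[n == 0] <- 0
  nbar <- rowSums(n) / r_eff
  sum_n <- rowSums(n)
  nc <- (sum_n - rowSums(n^2) / sum_n) / (r_eff - 1)
  pbar <- rowSums(n * p) / sum_n
  s2 <- rowSums(n * (p - pbar)^2) / ((r_eff - 1) * nbar)
  hbar <- rowSums(n * h) / sum_n
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r_eff - 1) / r_eff) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r_eff - 1) / r_eff) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  bad <- !is.finite(a) | !is.finite(b) | !is.finite(cc) | r_eff < 2
  a[bad] <- 0; b[bad] <- 0; cc[bad] <- 0
  list(a = a, b = b, c = cc)
}

# single-population b/c components (the within-population inbreeding f);
# returns per-locus b and c for one population
wc_single_pop_bc <- function(n, p, h) {
  ok <- n > 1
  b <- ifelse(ok, (n / (n - 1)) * (p * (1 - p) - ((2 * n - 1) / (4 * n)) * h), 0)
  cc <- ifelse(ok, h / 2, 0)
  list(b = b, c = cc)
}

# per-locus (n, p, h) matrices for a dataset, loci x populations
pop_locus_stats <- function(ds, pops = populations(ds)) {
  g <- ds$genotypes
  m <- ncol(g)
  n <- p <- h <- matrix(0, m, length(pops))
  for (k in seq_along(pops)) {
    sub <- g[pop_rows(ds, pops[k]), , drop = FALSE]
    nk <- colSums(!is.na(sub))
    n[, k] <- nk
    p[, k] <- ifelse(nk > 0, colSums(sub, na.rm = TRUE) / (2 * nk), NA)
    h[, k] <- ifelse(nk > 0, colMeans(sub == 1L, na.rm = TRUE), NA)
  }
  list(n = n, p = p, h = h, pops = pops)
}

#' Multi-locus Weir-Cockerham F-statistics
#'
#' Ratio-of-sums combining over loci: F_ST = sum(a) / sum(a+b+c),
#' F_IS = 1 - sum(c)/sum(b+c), F_IT = 1 - sum(c)/sum(a+b+c), so Wright's
#' identity (1-F_IT) = (1-F_IS)(1-F_ST) holds by construction.  Confidence
#' intervals bootstrap loci with replacement; permutation tests shuffle
#' population labels of individuals (F_ST) or re-pair allele copies within
#' populations (F_IS).
#'
#' @param ds a [genotype_dataset()] with >= 2 populations.
#' @param n_boot bootstrap replicates over loci (0 = no CIs).
#' @param n_perm permutation replicates (0 = no p-values).
#' @param seed integer RNG seed for resampling.
#' @param conf CI coverage (default 0.95, percentile method).
#' @return an `fstat_result` list: `fst`, `fis`, `fit`, optional `ci`
#'   (3 x 2 matrix) and `p_value` (named vector), plus resampling metadata.
#' @export
global_fstats <- function(ds, n_boot = 0, n_perm = 0, seed = 1, conf = 0.95) {
  validate_genotype_dataset(ds)
  pops <- populations(ds)
  if (length(pops) < 2) stop("need >= 2 populations")
  st <- pop_locus_stats(ds)
  comp <- wc_components_matrix(st$n, st$p, st$h)
  res <- fstats_from_components(comp)
  res$n_boot <- n_boot; res$n_perm <- n_perm; res$seed <- seed
  set.seed(seed)
  if (n_boot > 0) {
    m <- length(comp$a)
    boot <- matrix(NA_real_, n_boot, 3)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(m, m, replace = TRUE)
      boot[b, ] <- unlist(fstats_from_components(
        list(a = comp$a[idx], b = comp$b[idx], c = comp$c[idx]))[c("fst", "fis", "fit")])
    }
    alpha <- (1 - conf) / 2
    ci <- t(apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE))
    dimnames(ci) <- list(c("fst", "fis", "fit"), c("lo", "hi"))
    res$ci <- ci
  }
  if (n_perm > 0) {
    res$p_value <- c(
      fst = perm_pvalue_fst(ds, res$fst, n_perm),
      fis = perm_pvalue_fis(ds, res$fis, n_perm)
    )
  }
  class(res) <- "fstat_result"
  res
}

fstats_from_components <- function(comp) {
  tot <- sum(comp$a) + sum(comp$b) + sum(comp$c)
  list(fst = sum(comp$a) / tot,
       fis = 1 - sum(comp$c) / (sum(comp$b) + sum(comp$c)),
       fit = 1 - sum(comp$c) / tot)
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham F-statistics: F_ST = %.4f, F_IS = %.4f, F_IT = %.4f\n",
              x$fst, x$fis, x$fit))
  if (!is.null(x$ci)) {
    for (s in rownames(x$ci))
      cat(sprintf("  %s CI: [%.4f, %.4f]\n", s, x$ci[s, 1], x$ci[s, 2]))
  }
  if (!is.null(x$p_value))
    cat(sprintf("  permutation p: F_ST %.4g, F_IS %.4g\n",
                x$p_value["fst"], x$p_value["fis"]))
  invisible(x)
}

# permute population labels of individuals, recompute theta
perm_pvalue_fst <- function(ds, observed, n_perm) {
  hits <- 0
  perm_ds <- ds
  for (i in seq_len(n_perm)) {
    perm_ds$samples$population <- sample(ds$samples$population)
    st <- pop_locus_stats(perm_ds)
    theta <- fstats_from_components(wc_components_matrix(st$n, st$p, st$h))$fst
    if (!is.na(theta) && theta >= observed) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

# re-pair allele copies at random within each population (two-sided on |f|)
perm_pvalue_fis <- function(ds, observed, n_perm) {
  st <- pop_locus_stats(ds)
  hits <- 0
  for (i in seq_len(n_perm)) {
    h_perm <- st$h
    for (k in seq_len(ncol(st$n))) {
      nk <- st$n[, k]
      m1 <- round(2 * nk * st$p[, k])
      h_perm[, k] <- random_pairing_het(nk, m1)
    }
    comp <- wc_components_matrix(st$n, st$p, h_perm)
    f <- 1 - sum(comp$c) / (sum(comp$b) + sum(comp$c))
    if (!is.na(f) && abs(f) >= abs(observed)) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

# heterozygote fraction after randomly pairing 2n allele copies (m1 minor)
random_pairing_het <- function(n, m1) {
  out <- numeric(length(n))
  for (j in seq_along(n)) {
    if (n[j] < 1 || is.na(m1[j])) next
    alleles <- sample(rep(c(1L, 0L), c(m1[j], 2 * n[j] - m1[j])))
    out[j] <- mean(alleles[seq(1, 2 * n[j], 2)] != alleles[seq(2, 2 * n[j], 2)])
  }
  out
}

#' Pairwise F_ST matrix over populations
#'
#' Weir-Cockerham multi-locus theta for each population pair, using only the
#' two populations' genotypes.  Populations with fewer than 2 samples are
#' excluded with a warning.
#'
#' @param ds a [genotype_dataset()].
#' @return symmetric matrix with zero diagonal, labelled by population.
#' @export
pairwise_fst <- function(ds) {
  validate_genotype_dataset(ds)
  pops <- populations(ds)
  sizes <- table(ds$samples$population)[pops]
  if (any(sizes < 2)) {
    warning("excluding population(s) with < 2 samples: ",
            paste(pops[sizes < 2], collapse = ", "))
    pops <- pops[sizes >= 2]
  }
  K <- length(pops)
  if (K < 2) stop("need >= 2 populations with >= 2 samples")
  out <- matrix(0, K, K, dimnames = list(pops, pops))
  st <- pop_locus_stats(ds, pops)
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    comp <- wc_components_matrix(st$n[, c(i, j)], st$p[, c(i, j)], st$h[, c(i, j)])
    out[i, j] <- out[j, i] <- fstats_from_components(comp)$fst
  }
  out
}

#' Wright's identity
#'
#' Combines within-population inbreeding and among-population
#' differentiation into the total inbreeding coefficient:
#' F_IT = 1 - (1 - F_IS)(1 - F_ST).
#'
#' @param fis,fst fixation indices (< 1).
#' @return F_IT.
#' @export
wright_identity <- function(fis, fst) {
  stopifnot(fis < 1, fst < 1)
  1 - (1 - fis) * (1 - fst)
}
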