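#' Squared allelic correlation from haplotype frequencies
#'
#' r^2 = (P_ab - P_a P_b)^2 / (P_a (1 - P_a) P_b (1 - P_b)) for two loci with
#' allele frequencies `p_a`, `p_b` and haplotype frequency `p_ab`.
#'
#' @param p_a,p_b allele frequencies, strictly inside (0, 1).
#' @param p_ab frequency of the a-b haplotype.
#' @return r^2 in [0, 1]; `NA` with a warning for a monomorphic locus.
#' @export
r2_from_haplotypes <- function(p_a, p_b, p_ab) {
  if (p_a <= 0 || p_a >= 1 || p_b <= 0 || p_b >= 1) {
    warning("monomorphic locus: r^2 undefined")
    return(NA_real_)
  }
  (p_ab - p_a * p_b)^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
}

#' Maximum-likelihood haplotype frequencies from unphased genotype pairs
#'
#' The only ambiguous configuration at two biallelic loci is the double
#' heterozygote; EM resolves its phase starting from linkage equilibrium
#' (P_ab = P_a P_b), which is a deterministic initialization.
#'
#' @param g1,g2 dosage vectors at the two loci (0/1/2/NA); pairwise-complete
#'   individuals are used.
#' @param tol,max_iter EM controls.
#' @return list with `p_a`, `p_b`, `p_ab`, `n` (individuals used) and
#'   `converged`.
#' @export
estimate_haplotype_freqs <- function(g1, g2, tol = 1e-12, max_iter = 1000) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n < 1) stop("no pairwise-complete genotypes")
  cnt <- function(a, b) sum(g1 == a & g2 == b)
  n_dh <- cnt(1, 1)
  # unambiguous a-b haplotype copies
  fixed_ab <- 2 * cnt(2, 2) + cnt(2, 1) + cnt(1, 2)
  p_a <- mean(g1) / 2
  p_b <- mean(g2) / 2
  p_ab <- p_a * p_b
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    p_Ab <- p_a - p_ab
    p_aB <- p_b - p_ab
    p_00 <- 1 - p_a - p_b + p_ab
    num <- p_ab * p_00
    den <- num + p_Ab * p_aB
    w <- if (den > 0) num / den else 0.5   # P(double het is ab/AB phase)
    p_new <- (fixed_ab + n_dh * w) / (2 * n)
    if (abs(p_new - p_ab) < tol) { p_ab <- p_new; converged <- TRUE; break }
    p_ab <- p_new
  }
  if (!converged && n_dh == 0) converged <- TRUE
  list(p_a = p_a, p_b = p_b, p_ab = p_ab, n = n, converged = converged)
}

#' The 20-bin LD decay distance scheme
#'
#' Half-open edges in bp: [0,1) kb, ten-kb steps from 1 kb to 100 kb, then
#' hundred-kb steps from 100 kb to 1 Mb -- 20 bins in total.
#'
#' @return numeric vector of 21 bin edges in bp.
#' @export
ld_bins_default <- function() {
  c(0, 1e3, seq(1e4, 1e5, by = 1e4), seq(2e5, 1e6, by = 1e5))
}

#' Log-spaced distance bins for N_e estimation
#'
#' @param lo_bp,hi_bp range (defaults 10 kb to 4 Mb).
#' @param n number of bins.
#' @return numeric vector of `n + 1` edges in bp.
#' @export
ne_bins_logspaced <- function(lo_bp = 1e4, hi_bp = 4e6, n = 20) {
  exp(seq(log(lo_bp), log(hi_bp), length.out = n + 1))
}

#' Binned LD decay within one population
#'
#' All intra-chromosomal SNP pairs closer than `max_distance_bp` are scored
#' with r^2 (EM haplotype frequencies by default, or the squared dosage
#' correlation with `method = "composite"`) and averaged within half-open
#' distance bins.  Loci monomorphic in the population are skipped.
#'
#' @param ds a [genotype_dataset()].
#' @param population population label (default: all samples pooled).
#' @param max_distance_bp maximum pair distance considered.
#' @param breaks bin edges in bp (default [ld_bins_default()]).
#' @param method `"em"` or `"composite"`.
#' @param min_maf skip loci below this within-population MAF (default 0).
#' @return data.frame of `ld_bin` rows: `lo_bp`, `hi_bp`,
#'   `representative_distance` (midpoint), `mean_r2`, `n_pairs`; empty bins
#'   keep `n_pairs = 0` and `mean_r2 = NA`.
#' @export
ld_decay <- function(ds, population = NULL, max_distance_bp = 1e6,
                     breaks = ld_bins_default(), method = c("em", "composite"),
                     min_maf = 0) {
  validate_genotype_dataset(ds)
  method <- match.arg(method)
  rows <- if (is.null(population)) seq_len(n_samples(ds)) else pop_rows(ds, population)
  g <- ds$genotypes[rows, , drop = FALSE]
  freq <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  keep <- !is.na(maf) & maf > min_maf & freq > 0 & freq < 1
  g <- g[, keep, drop = FALSE]
  snps <- ds$snps[keep, , drop = FALSE]
  breaks <- sort(breaks)
  nb <- length(breaks) - 1
  sums <- counts <- numeric(nb)
  for (chr in unique(snps$chrom)) {
    on_chr <- which(snps$chrom == chr)
    pos <- snps$pos[on_chr]
    mm <- length(on_chr)
    if (mm < 2) next
    for (i in seq_len(mm - 1)) {
      j <- i + 1
      while (j <= mm && pos[j] - pos[i] <= max_distance_bp) {
        dist <- pos[j] - pos[i]
        bin <- findInterval(dist, breaks, rightmost.closed = TRUE)
        if (bin >= 1 && bin <= nb) {
          r2 <- pair_r2(g[, on_chr[i]], g[, on_chr[j]], method)
          if (!is.na(r2)) {
            sums[bin] <- sums[bin] + r2
            counts[bin] <- counts[bin] + 1
          }
        }
        j <- j + 1
      }
    }
  }
  data.frame(lo_bp = breaks[-length(breaks)], hi_bp = breaks[-1],
             representative_distance = (breaks[-length(breaks)] + breaks[-1]) / 2,
             mean_r2 = ifelse(counts > 0, sums / counts, NA),
             n_pairs = as.integer(counts))
}

pair_r2 <- function(g1, g2, method) {
  if (method == "composite") {
    r <- suppressWarnings(stats::cor(g1, g2, use = "pairwise.complete.obs"))
    return(if (is.na(r)) NA_real_ else r^2)
  }
  hf <- estimate_haplotype_freqs(g1, g2)
  if (hf$p_a <= 0 || hf$p_a >= 1 || hf$p_b <= 0 || hf$p_b >= 1) return(NA_real_)
  r2_from_haplotypes(hf$p_a, hf$p_b, hf$p_ab)
}

#' Sved's mapping between recombination fraction and expected LD
#'
#' f(c) = c (1 - c/2) / (1 - c)^2.
#'
#' @param c recombination fraction in (0, 1).
#' @return f(c).
#' @export
sved_f <- function(c) {
  if (any(c >= 1) || any(c <= 0)) stop("recombination fraction must be in (0, 1)")
  c * (1 - c / 2) / (1 - c)^2
}

#' LD-based historical effective population size
#'
#' Converts binned mean r^2 into a trajectory of past effective sizes:
#' each bin's representative distance maps to a recombination fraction
#' c = distance_bp * cm_per_mb * 1e-8, the time horizon is t = 1/(2c)
#' generations ago (rounded to integer), the sample-size-adjusted LD is
#' r2_adj = mean_r2 - 1/(2 n_sample), and
#' N(t) = (4 f(c))^{-1} (1/r2_adj - alpha), with Sved's f and a mutation
#' correction constant alpha (1, 2 or 2.2; default 2.2).  Bins where the
#' adjusted LD would imply a negative size are dropped with a warning.
#'
#' @param bins data.frame from [ld_decay()] (any break scheme).
#' @param n_sample diploid sample size behind the r^2 values.
#' @param alpha mutation correction constant.
#' @param cm_per_mb genetic map density (default 1 cM/Mb).
#' @return data.frame sorted by `t` ascending: `t`, `ne`, `c_t`,
#'   `mean_r2_adj`, `n_pairs`.
#' @export
ne_trajectory <- function(bins, n_sample, alpha = 2.2, cm_per_mb = 1) {
  stopifnot(nrow(bins) > 0, n_sample >= 2)
  use <- bins$n_pairs > 0 & !is.na(bins$mean_r2)
  bins <- bins[use, , drop = FALSE]
  if (nrow(bins) == 0) stop("no bins with defined mean r^2")
  c_t <- bins$representative_distance * cm_per_mb * 1e-8
  r2_adj <- bins$mean_r2 - 1 / (2 * n_sample)
  ok <- r2_adj > 0 & (1 / r2_adj) > alpha & c_t < 1
  if (any(!ok))
    warning(sum(!ok), " bin(s) dropped: adjusted r^2 implies negative N_e")
  out <- data.frame(
    t = round(1 / (2 * c_t[ok])),
    ne = (1 / (4 * sved_f(c_t[ok]))) * (1 / r2_adj[ok] - alpha),
    c_t = c_t[ok], mean_r2_adj = r2_adj[ok], n_pairs = bins$n_pairs[ok]
  )
  out[order(out$t), , drop = FALSE]
}
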