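#' Call-rate quality control
#'
#' Removes SNPs with call rate below `snp_call_rate` first, then samples
#' whose call rate over the *surviving* SNPs falls below `sample_call_rate`.
#' The order matters with patterned missingness and is fixed (SNPs first) so
#' results are deterministic.
#'
#' @param ds a [genotype_dataset()].
#' @param snp_call_rate minimum fraction of non-missing calls per SNP.
#' @param sample_call_rate minimum fraction of non-missing calls per sample.
#' @return list with `dataset` (filtered) and `report` (a `qc_report` with
#'   removed/kept counts and the thresholds used).
#' @export
qc_filter <- function(ds, snp_call_rate = 0.95, sample_call_rate = 0.95) {
  validate_genotype_dataset(ds)
  stopifnot(snp_call_rate > 0, snp_call_rate <= 1,
            sample_call_rate > 0, sample_call_rate <= 1)
  g <- ds$genotypes
  n0_snp <- ncol(g); n0_samp <- nrow(g)
  snp_cr <- colMeans(!is.na(g))
  keep_snp <- snp_cr >= snp_call_rate
  g2 <- g[, keep_snp, drop = FALSE]
  samp_cr <- if (ncol(g2) > 0) rowMeans(!is.na(g2)) else rep(1, nrow(g2))
  keep_samp <- samp_cr >= sample_call_rate
  out <- subset_dataset(ds, samples = which(keep_samp), snps = which(keep_snp))
  report <- structure(list(
    snps_removed = sum(!keep_snp), snps_kept = sum(keep_snp),
    samples_removed = sum(!keep_samp), samples_kept = sum(keep_samp),
    snp_call_rate = snp_call_rate, sample_call_rate = sample_call_rate
  ), class = "qc_report")
  stopifnot(report$snps_removed + report$snps_kept == n0_snp,
            report$samples_removed + report$samples_kept == n0_samp)
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: removed %d/%d SNPs (call rate < %.2f), %d/%d samples (call rate < %.2f)\n",
              x$snps_removed, x$snps_removed + x$snps_kept, x$snp_call_rate,
              x$samples_removed, x$samples_removed + x$samples_kept,
              x$sample_call_rate))
  invisible(x)
}

#' Windowed greedy LD pruning
#'
#' Mirrors the pairwise pruning scheme of standard GWAS toolkits: per
#' chromosome, slide a window of `window_snps` markers by `step_snps`; within
#' each window, while any retained pair has squared dosage correlation above
#' `r2_threshold`, drop the member of the worst offending pair with the lower
#' pooled MAF (ties drop the later map position).  r-squared is the composite
#' (genotypic) correlation over pairwise-complete samples.
#'
#' Note the community default threshold is 0.2; values above 1 are impossible
#' for r-squared and rejected.
#'
#' @param ds a [genotype_dataset()].
#' @param window_snps window size in SNPs (>= 2).
#' @param step_snps slide step in SNPs.
#' @param r2_threshold prune when pairwise r-squared exceeds this (in (0, 1]).
#' @return sorted integer vector of retained SNP column indices.
#' @export
ld_prune <- function(ds, window_snps = 50, step_snps = 5, r2_threshold = 0.2) {
  validate_genotype_dataset(ds)
  if (window_snps < 2) stop("window_snps must be >= 2")
  if (!(r2_threshold > 0 && r2_threshold <= 1))
    stop("r2_threshold must be in (0, 1]; note r-squared cannot exceed 1")
  g <- ds$genotypes
  maf <- pmin(colMeans(g, na.rm = TRUE) / 2,
              1 - colMeans(g, na.rm = TRUE) / 2)
  keep <- rep(TRUE, ncol(g))
  for (chr in unique(ds$snps$chrom)) {
    idx <- which(ds$snps$chrom == chr)
    start <- 1
    repeat {
      win <- idx[start:min(start + window_snps - 1, length(idx))]
      keep <- prune_window(g, win, keep, maf, ds$snps$pos, r2_threshold)
      if (start + window_snps - 1 >= length(idx)) break
      start <- start + step_snps
    }
  }
  which(keep)
}

prune_window <- function(g, win, keep, maf, pos, r2_threshold) {
  repeat {
    act <- win[keep[win]]
    if (length(act) < 2) return(keep)
    r2 <- suppressWarnings(stats::cor(g[, act, drop = FALSE],
                                      use = "pairwise.complete.obs"))^2
    diag(r2) <- 0
    r2[is.na(r2)] <- 0
    worst <- max(r2)
    if (worst <= r2_threshold) return(keep)
    hit <- which(r2 == worst, arr.ind = TRUE)[1, ]
    i <- act[hit[1]]; j <- act[hit[2]]
    drop <- if (maf[i] < maf[j]) i
    else if (maf[j] < maf[i]) j
    else if (pos[i] > pos[j]) i else j
    keep[drop] <- FALSE
  }
}
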