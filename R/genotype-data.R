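#' Construct a genotype dataset
#'
#' The universal container for all estimators in the package: a samples x
#' SNPs matrix of minor-allele dosages in \{0, 1, 2\} with `NA` as the
#' missing-call sentinel, plus a SNP map and per-sample population labels.
#'
#' SNPs are kept sorted by (chromosome, position).  The dosage orientation
#' (which allele is counted) is fixed once, at load or simulation time, from
#' the pooled frequency over all samples; per-population frequencies computed
#' downstream inherit that orientation, so a "minor" allele may exceed 0.5
#' within a single population.
#'
#' @param genotypes integer matrix, samples in rows, SNPs in columns; entries
#'   0, 1, 2 or NA.
#' @param snps data.frame with columns `id`, `chrom`, `pos`, `allele_a`,
#'   `allele_b`; one row per SNP column. `allele_a` is the counted allele.
#' @param samples data.frame with columns `id`, `population`; one row per
#'   matrix row.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, snps, samples) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  ds <- structure(
    list(genotypes = genotypes, snps = snps, samples = samples),
    class = "genotype_dataset"
  )
  validate_genotype_dataset(ds)
  # keep the map sorted by (chrom, pos)
  ord <- order(ds$snps$chrom, ds$snps$pos)
  if (is.unsorted(ord)) {
    ds$snps <- ds$snps[ord, , drop = FALSE]
    rownames(ds$snps) <- NULL
    ds$genotypes <- ds$genotypes[, ord, drop = FALSE]
  }
  dimnames(ds$genotypes) <- list(ds$samples$id, ds$snps$id)
  ds
}

validate_genotype_dataset <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  g <- ds$genotypes
  if (nrow(g) != nrow(ds$samples))
    stop("sample count does not match genotype matrix rows")
  if (ncol(g) != nrow(ds$snps))
    stop("SNP count does not match genotype matrix columns")
  bad <- !(is.na(g) | g == 0L | g == 1L | g == 2L)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  req_snp <- c("id", "chrom", "pos", "allele_a", "allele_b")
  if (!all(req_snp %in% names(ds$snps)))
    stop("snps must have columns ", paste(req_snp, collapse = ", "))
  if (!all(c("id", "population") %in% names(ds$samples)))
    stop("samples must have columns id, population")
  if (nrow(ds$snps) > 0 && any(ds$snps$pos < 1))
    stop("positions must be >= 1")
  if (nrow(ds$samples) > 0 && any(!nzchar(ds$samples$population)))
    stop("population labels must be non-empty")
  invisible(ds)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf(
    "genotype_dataset: %d samples x %d SNPs, %d population(s)\n",
    nrow(x$genotypes), ncol(x$genotypes),
    length(unique(x$samples$population))
  ))
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples / SNPs in a dataset
#' @param ds a `genotype_dataset`
#' @return integer count.
#' @export
n_samples <- function(ds) nrow(ds$genotypes)

#' @rdname n_samples
#' @export
n_snps <- function(ds) ncol(ds$genotypes)

#' Population labels present in a dataset
#' @param ds a `genotype_dataset`
#' @return character vector of unique labels in order of first appearance.
#' @export
populations <- function(ds) unique(ds$samples$population)

#' Subset a genotype dataset
#'
#' @param ds a `genotype_dataset`
#' @param samples integer or logical index over samples (optional)
#' @param snps integer or logical index over SNPs (optional)
#' @return the subsetted `genotype_dataset`.
#' @export
subset_dataset <- function(ds, samples = NULL, snps = NULL) {
  g <- ds$genotypes
  sm <- ds$samples
  sp <- ds$snps
  if (!is.null(samples)) {
    g <- g[samples, , drop = FALSE]
    sm <- sm[samples, , drop = FALSE]
  }
  if (!is.null(snps)) {
    g <- g[, snps, drop = FALSE]
    sp <- sp[snps, , drop = FALSE]
  }
  rownames(sm) <- NULL
  rownames(sp) <- NULL
  genotype_dataset(g, sp, sm)
}

# rows of the genotype matrix belonging to one population
pop_rows <- function(ds, population) {
  idx <- which(ds$samples$population == population)
  if (length(idx) == 0) stop("unknown population label: ", population)
  idx
}
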