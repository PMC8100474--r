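#' Read genotypes from PLINK-layout files
#'
#' Supports the text pair `.ped`/`.map` and the binary triplet
#' `.bed`/`.bim`/`.fam` (SNP-major bed, v1.00 magic).  The family ID column
#' holds the population label.  Non-autosomal markers (chromosome labels that
#' are not positive integers, e.g. "X", "MT", "0") are dropped with a
#' warning.  After loading, each SNP is oriented so that the counted allele
#' (`allele_a`) is the pooled minor allele; exact 50/50 ties keep the
#' orientation the file declared.
#'
#' @param path_prefix path without extension.
#' @param dialect `"plink-text"` or `"plink-binary"`.
#' @return a [genotype_dataset()].
#' @export
read_genotypes <- function(path_prefix, dialect = c("plink-binary", "plink-text")) {
  dialect <- match.arg(dialect)
  if (dialect == "plink-text") {
    ds <- read_plink_text(path_prefix)
  } else {
    ds <- read_plink_binary(path_prefix)
  }
  orient_minor(ds)
}

#' Write genotypes to PLINK-layout files
#'
#' Inverse of [read_genotypes()]: `read(write(ds))` reproduces the dosage
#' matrix, SNP map and sample labels exactly (up to minor-allele
#' re-orientation at 50/50 loci).  Missing calls are written as `0 0` allele
#' pairs (text) or the `01` two-bit code (binary).
#'
#' @param ds a [genotype_dataset()].
#' @param path_prefix output path without extension.
#' @param dialect `"plink-text"` or `"plink-binary"`.
#' @export
write_genotypes <- function(ds, path_prefix, dialect = c("plink-binary", "plink-text")) {
  validate_genotype_dataset(ds)
  dialect <- match.arg(dialect)
  if (dialect == "plink-text") write_plink_text(ds, path_prefix)
  else write_plink_binary(ds, path_prefix)
  invisible(NULL)
}

# ---- internal helpers -----------------------------------------------------

is_autosome <- function(chrom) grepl("^[0-9]+$", chrom) & suppressWarnings(as.integer(chrom)) >= 1

drop_non_autosomes <- function(snp_tab) {
  keep <- is_autosome(snp_tab$chrom)
  if (!all(keep)) {
    warning(sum(!keep), " non-autosomal SNP(s) skipped")
  }
  keep
}

# flip each SNP so the counted allele is the pooled minor allele;
# ties (freq exactly 0.5) keep allele_a as declared
orient_minor <- function(ds) {
  g <- ds$genotypes
  freq <- colMeans(g, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  if (any(flip)) {
    g[, flip] <- 2L - g[, flip]
    tmp <- ds$snps$allele_a[flip]
    ds$snps$allele_a[flip] <- ds$snps$allele_b[flip]
    ds$snps$allele_b[flip] <- tmp
    ds$genotypes <- g
  }
  ds
}

read_plink_text <- function(prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  if (!file.exists(map_path) || !file.exists(ped_path))
    stop("missing .ped/.map pair at prefix ", prefix)
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character", "character", "integer"))
  names(map) <- c("chrom", "id", "cm", "pos")
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  n_fields <- 6 + 2 * nrow(map)
  if (length(toks) > 0 && any(lengths(toks) != n_fields))
    stop("format error: .ped rows do not match .map SNP count")
  fam <- t(vapply(toks, function(x) x[1:6], character(6)))
  m <- nrow(map)
  n <- length(toks)
  g <- matrix(NA_integer_, n, m)
  allele_a <- allele_b <- character(m)
  if (n > 0) {
    amat <- t(vapply(toks, function(x) x[-(1:6)], character(2 * m)))
    for (j in seq_len(m)) {
      a1 <- amat[, 2 * j - 1]
      a2 <- amat[, 2 * j]
      seen <- unique(c(a1, a2))
      seen <- sort(seen[seen != "0"], method = "radix")  # deterministic order
      if (length(seen) > 2)
        stop("format error: more than two alleles at SNP ", map$id[j])
      aa <- if (length(seen) >= 1) seen[1] else "0"
      ab <- if (length(seen) == 2) seen[2] else "0"
      allele_a[j] <- aa
      allele_b[j] <- ab
      ok <- a1 != "0" & a2 != "0"
      g[ok, j] <- (a1[ok] == aa) + (a2[ok] == aa)
    }
  }
  snps <- data.frame(id = map$id, chrom = map$chrom, pos = map$pos,
                     allele_a = allele_a, allele_b = allele_b,
                     stringsAsFactors = FALSE)
  keep <- drop_non_autosomes(snps)
  snps <- snps[keep, , drop = FALSE]
  snps$chrom <- as.integer(snps$chrom)
  g <- g[, keep, drop = FALSE]
  samples <- data.frame(id = if (n > 0) fam[, 2] else character(),
                        population = if (n > 0) fam[, 1] else character(),
                        stringsAsFactors = FALSE)
  genotype_dataset(g, snps, samples)
}

write_plink_text <- function(ds, prefix) {
  snps <- ds$snps
  map <- data.frame(snps$chrom, snps$id, rep(0L, nrow(snps)), snps$pos)
  utils::write.table(map, paste0(prefix, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  g <- ds$genotypes
  n <- nrow(g); m <- ncol(g)
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    al <- character(2 * m)
    if (m > 0) {
      for (j in seq_len(m)) {
        d <- g[i, j]
        pair <- if (is.na(d)) c("0", "0")
        else if (d == 2L) rep(snps$allele_a[j], 2)
        else if (d == 1L) c(snps$allele_a[j], snps$allele_b[j])
        else rep(snps$allele_b[j], 2)
        al[c(2 * j - 1, 2 * j)] <- pair
      }
    }
    row <- c(ds$samples$population[i], ds$samples$id[i], "0", "0", "0", "-9", al)
    writeLines(paste(row, collapse = " "), con)
  }
  invisible(NULL)
}

read_plink_binary <- function(prefix) {
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  bed_path <- paste0(prefix, ".bed")
  for (p in c(bim_path, fam_path, bed_path))
    if (!file.exists(p)) stop("missing file ", p)
  bim <- utils::read.table(bim_path, header = FALSE, colClasses = "character")
  names(bim) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  fam <- utils::read.table(fam_path, header = FALSE, colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("format error: not a v1.00 bed file")
  if (raw[3] != as.raw(0x01))
    stop("format error: bed file is not SNP-major")
  bpp <- ceiling(n / 4)  # bytes per SNP
  if (length(raw) - 3 != bpp * m)
    stop("format error: bed size inconsistent with .bim/.fam counts")
  # decode two-bit codes: 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> NA
  code_map <- c(2L, NA_integer_, 1L, 0L)  # indexed by code 0..3
  body <- as.integer(raw[-(1:3)])
  g <- matrix(NA_integer_, n, m)
  shifts <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(m)) {
    bytes <- body[((j - 1) * bpp + 1):(j * bpp)]
    codes <- integer(4 * bpp)
    for (s in 0:3) codes[seq(s + 1, by = 4, length.out = bpp)] <-
        (bytes %/% shifts[s + 1]) %% 4L
    g[, j] <- code_map[codes[seq_len(n)] + 1L]
  }
  snps <- data.frame(id = bim$id, chrom = bim$chrom,
                     pos = as.integer(bim$pos),
                     allele_a = bim$a1, allele_b = bim$a2,
                     stringsAsFactors = FALSE)
  keep <- drop_non_autosomes(snps)
  snps <- snps[keep, , drop = FALSE]
  snps$chrom <- as.integer(snps$chrom)
  g <- g[, keep, drop = FALSE]
  samples <- data.frame(id = fam[, 2], population = fam[, 1],
                        stringsAsFactors = FALSE)
  genotype_dataset(g, snps, samples)
}

write_plink_binary <- function(ds, prefix) {
  snps <- ds$snps
  bim <- data.frame(snps$chrom, snps$id, rep(0L, nrow(snps)), snps$pos,
                    snps$allele_a, snps$allele_b)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  nsamp <- nrow(ds$samples)
  fam <- data.frame(ds$samples$population, ds$samples$id, rep(0L, nsamp),
                    rep(0L, nsamp), rep(0L, nsamp), rep(-9L, nsamp))
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  g <- ds$genotypes
  n <- nrow(g); m <- ncol(g)
  bpp <- ceiling(n / 4)
  # dosage -> two-bit code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  dose_code <- function(d) ifelse(is.na(d), 1L, c(3L, 2L, 0L)[d + 1L])
  out <- raw(3 + bpp * m)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  shifts <- c(1L, 4L, 16L, 64L)
  for (j in seq_len(m)) {
    codes <- integer(4 * bpp)
    if (n > 0) codes[seq_len(n)] <- dose_code(g[, j])
    bytes <- integer(bpp)
    for (s in 0:3) bytes <- bytes + codes[seq(s + 1, by = 4, length.out = bpp)] * shifts[s + 1]
    out[(3 + (j - 1) * bpp + 1):(3 + j * bpp)] <- as.raw(bytes)
  }
  writeBin(out, paste0(prefix, ".bed"))
  invisible(NULL)
}
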