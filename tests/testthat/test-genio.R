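test_that("text fileset round-trips and preserves shape", {
  g <- rbind(c(0L, 1L, 2L), c(2L, NA, 0L))
  ds <- make_ds(g, c("hanwoo", "angus"))
  prefix <- file.path(withr::local_tempdir(), "toy")
  write_genotypes(ds, prefix, "plink-text")
  back <- read_genotypes(prefix, "plink-text")
  expect_equal(dim(back$genotypes), c(2L, 3L))
  expect_equal(unname(back$genotypes), unname(ds$genotypes))
  expect_equal(back$samples$population, ds$samples$population)
  expect_equal(back$snps$pos, ds$snps$pos)
})

test_that("binary fileset round-trips dosages, missing calls and labels", {
  set.seed(42)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 9 * 17, replace = TRUE,
                     prob = c(.4, .3, .2, .1)), 9, 17)
  ds <- make_ds(g, rep(c("a", "b", "c"), each = 3))
  ds <- herdchar:::orient_minor(ds)  # canonical orientation before writing
  prefix <- file.path(withr::local_tempdir(), "bin")
  write_genotypes(ds, prefix, "plink-binary")
  back <- read_genotypes(prefix, "plink-binary")
  expect_identical(unname(back$genotypes), unname(ds$genotypes))
  expect_equal(back$samples$id, ds$samples$id)
  expect_equal(back$snps$allele_a, ds$snps$allele_a)
})

test_that("the two dialects agree with each other", {
  set.seed(7)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 60, replace = TRUE), 6, 10)
  ds <- herdchar:::orient_minor(make_ds(g, rep(c("x", "y"), 3)))
  dir <- withr::local_tempdir()
  write_genotypes(ds, file.path(dir, "t"), "plink-text")
  write_genotypes(ds, file.path(dir, "b"), "plink-binary")
  t_ds <- read_genotypes(file.path(dir, "t"), "plink-text")
  b_ds <- read_genotypes(file.path(dir, "b"), "plink-binary")
  expect_identical(unname(t_ds$genotypes), unname(b_ds$genotypes))
})

test_that("non-autosomal SNPs are skipped with a warning", {
  dir <- withr::local_tempdir()
  writeLines(c("1\ts1\t0\t100", "X\tsX\t0\t200", "2\ts2\t0\t300"),
             file.path(dir, "sex.map"))
  writeLines(c("p1 i1 0 0 0 -9 A A A C G G",
               "p1 i2 0 0 0 -9 A C C C G T"),
             file.path(dir, "sex.ped"))
  expect_warning(ds <- read_genotypes(file.path(dir, "sex"), "plink-text"),
                 "non-autosomal")
  expect_equal(n_snps(ds), 2L)
  expect_false("sX" %in% ds$snps$id)
})

test_that("empty-SNP dataset writes and validates", {
  ds <- make_ds(matrix(integer(), 2, 0), c("a", "b"))
  prefix <- file.path(withr::local_tempdir(), "empty")
  expect_silent(write_genotypes(ds, prefix, "plink-binary"))
  expect_true(file.exists(paste0(prefix, ".bed")))
})

test_that("minor-allele orientation is pooled and flips dosages", {
  # counted allele at load has frequency 0.75 -> must be flipped to 0.25
  g <- rbind(c(2L), c(2L), c(1L), c(1L))
  ds <- make_ds(g, rep("p", 4))
  prefix <- file.path(withr::local_tempdir(), "flip")
  write_genotypes(ds, prefix, "plink-text")
  back <- read_genotypes(prefix, "plink-text")
  expect_equal(mean(back$genotypes) / 2, 0.25)
})

test_that("call-rate filter removes SNPs then samples, and reports counts", {
  # SNP 1: 9/10 calls -> removed at 0.95; others complete
  g <- matrix(1L, 10, 4)
  g[1, 1] <- NA
  ds <- make_ds(g, rep("p", 10))
  out <- qc_filter(ds, 0.95, 0.95)
  expect_equal(out$report$snps_removed, 1L)
  expect_equal(out$report$samples_removed, 0L)
  expect_equal(n_snps(out$dataset), 3L)
})

test_that("qc_filter matches hand-enumerated call rates on a designed fixture", {
  set.seed(11)
  g <- matrix(sample(c(0L, 1L, 2L), 20 * 30, replace = TRUE), 20, 30)
  # SNPs 1-4 get 3 missing calls each (rate 0.85 < 0.9); sample 5 loses
  # many of the surviving SNPs
  for (j in 1:4) g[sample(20, 3), j] <- NA
  g[5, 5:20] <- NA
  ds <- make_ds(g, rep(c("a", "b"), 10))
  out <- qc_filter(ds, snp_call_rate = 0.9, sample_call_rate = 0.9)
  # oracle: enumerate by hand
  snp_keep <- colMeans(!is.na(g)) >= 0.9
  samp_keep <- rowMeans(!is.na(g[, snp_keep])) >= 0.9
  expect_equal(out$report$snps_kept, sum(snp_keep))
  expect_equal(out$report$samples_kept, sum(samp_keep))
  expect_equal(unname(out$dataset$genotypes),
               unname(g[samp_keep, snp_keep]))
})

test_that("qc_filter is idempotent and tolerates removing everything", {
  g <- matrix(NA_integer_, 4, 3)
  g[1, ] <- 1L
  ds <- make_ds(g, rep("p", 4))
  once <- qc_filter(ds, 0.95, 0.95)
  expect_equal(n_snps(once$dataset), 0L)  # empty result, not an error
  clean <- make_ds(matrix(1L, 4, 3), rep("p", 4))
  a <- qc_filter(clean, 0.95, 0.95)
  b <- qc_filter(a$dataset, 0.95, 0.95)
  expect_identical(a$dataset$genotypes, b$dataset$genotypes)
  expect_equal(b$report$snps_removed, 0L)
})

test_that("duplicated SNPs in perfect LD are pruned down to one", {
  set.seed(1)
  x <- sample(c(0L, 1L, 2L), 30, replace = TRUE)
  y <- sample(c(0L, 1L, 2L), 30, replace = TRUE)
  ds <- make_ds(cbind(x, x, y), rep("p", 30))
  kept <- ld_prune(ds, window_snps = 10, step_snps = 5, r2_threshold = 0.2)
  expect_length(intersect(kept, 1:2), 1)
  expect_true(3 %in% kept)
})

test_that("independent SNPs are all retained", {
  set.seed(2)
  g <- matrix(rbinom(40 * 12, 2, 0.4), 40, 12)
  ds <- make_ds(g, rep("p", 40))
  kept <- ld_prune(ds, 6, 3, 0.9)
  expect_equal(kept, 1:12)
})

test_that("windowed pruning equals the exhaustive greedy oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 25
    base <- rbinom(n, 2, 0.5)
    g <- sapply(1:10, function(j) {
      # correlated block structure to force prune decisions
      mix <- rbinom(n, 1, 0.35)
      ifelse(mix == 1, rbinom(n, 2, 0.5), base)
    })
    storage.mode(g) <- "integer"
    ds <- make_ds(g, rep("p", n))
    kept <- ld_prune(ds, window_snps = 5, step_snps = 2, r2_threshold = 0.3)
    oracle <- prune_oracle(ds$genotypes, ds$snps$chrom, ds$snps$pos,
                           window = 5, step = 2, thr = 0.3)
    expect_equal(kept, oracle, info = paste("seed", seed))
    # invariant: no retained within-window pair above threshold
    expect_true(all(diff(kept) >= 0))
  }
})

test_that("an r2 threshold above 1 is rejected as impossible", {
  ds <- make_ds(matrix(1L, 4, 4), rep("p", 4))
  expect_error(ld_prune(ds, 4, 2, 2), "r2_threshold")
})
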