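test_that("r-squared closed forms from haplotype frequencies", {
  expect_equal(r2_from_haplotypes(0.5, 0.5, 0.25), 0)   # independence
  expect_equal(r2_from_haplotypes(0.5, 0.5, 0.5), 1)    # complete association
  expect_equal(r2_from_haplotypes(0.4, 0.3, 0.2),
               (0.2 - 0.12)^2 / (0.24 * 0.21))
  expect_warning(r2 <- r2_from_haplotypes(0, 0.5, 0), "monomorphic")
  expect_true(is.na(r2))
})

test_that("haplotype EM reduces to counting without double heterozygotes", {
  g1 <- c(0L, 0L, 2L, 2L, 1L, 0L)
  g2 <- c(0L, 0L, 2L, 2L, 0L, 1L)
  hf <- estimate_haplotype_freqs(g1, g2)
  # haplotype copies are unambiguous here: count them directly
  expect_equal(hf$p_ab, 4 / 12)
  expect_equal(hf$p_a, 5 / 12)
  expect_true(hf$converged)
})

test_that("phase-consistent fixtures are recovered exactly", {
  # construct genotypes from known haplotypes: AB x 6, ab x 4, Ab x 2
  haps <- rbind(matrix(c(1, 1), 6, 2, byrow = TRUE),
                matrix(c(0, 0), 4, 2, byrow = TRUE),
                matrix(c(1, 0), 2, 2, byrow = TRUE))
  set.seed(5)
  # pair haplotypes that avoid double heterozygotes so phase is determined
  ord <- c(1:6, 7:12)
  g1 <- haps[ord[seq(1, 12, 2)], 1] + haps[ord[seq(2, 12, 2)], 1]
  g2 <- haps[ord[seq(1, 12, 2)], 2] + haps[ord[seq(2, 12, 2)], 2]
  hf <- estimate_haplotype_freqs(as.integer(g1), as.integer(g2))
  expect_equal(hf$p_ab, 6 / 12, tolerance = 1e-9)
})

test_that("symmetric double-heterozygote-only input sits at the
           equilibrium fixed point", {
  g1 <- rep(1L, 10)
  g2 <- rep(1L, 10)
  hf <- estimate_haplotype_freqs(g1, g2)
  expect_equal(hf$p_ab, hf$p_a * hf$p_b, tolerance = 1e-9)
})

test_that("EM r-squared equals squared dosage correlation on
           phase-unambiguous data", {
  set.seed(7)
  hap_freq <- c(AB = 0.4, Ab = 0.1, aB = 0.2, ab = 0.3)
  draw <- sample(names(hap_freq), 400, replace = TRUE, prob = hap_freq)
  h1 <- as.integer(draw %in% c("AB", "Ab"))
  h2 <- as.integer(draw %in% c("AB", "aB"))
  g1 <- h1[seq(1, 400, 2)] + h1[seq(2, 400, 2)]
  g2 <- h2[seq(1, 400, 2)] + h2[seq(2, 400, 2)]
  hf <- estimate_haplotype_freqs(g1, g2)
  r2_em <- r2_from_haplotypes(hf$p_a, hf$p_b, hf$p_ab)
  r2_comp <- cor(g1, g2)^2
  expect_equal(r2_em, r2_comp, tolerance = 0.05)
})

test_that("the decay bin scheme is the 20-interval ladder", {
  br <- ld_bins_default()
  expect_length(br, 21)
  expect_equal(br[1:3], c(0, 1e3, 1e4))
  expect_equal(br[12:13], c(1e5, 2e5))
  expect_equal(br[21], 1e6)
})

test_that("a duplicated SNP at 500 bp contributes r2 = 1 to the first bin", {
  set.seed(9)
  x <- as.integer(rbinom(30, 2, 0.4))
  g <- cbind(x, x)
  ds <- make_ds(g, rep("p", 30), pos = c(1000L, 1500L))
  bins <- ld_decay(ds)
  expect_equal(bins$n_pairs[1], 1L)
  expect_equal(bins$mean_r2[1], 1)
  expect_equal(sum(bins$n_pairs), 1L)
})

test_that("recombination produces decaying LD across distance bins", {
  ds <- simulate_wright_fisher(data.frame(gens = 120, ne = 50), 1e6, 1e-6,
                               150, 40, seed = 101)
  bins <- ld_decay(ds, max_distance_bp = 1e6, min_maf = 0.05)
  ok <- bins$n_pairs >= 5
  expect_gt(sum(ok), 5)
  rho <- cor(bins$representative_distance[ok], bins$mean_r2[ok],
             method = "spearman")
  expect_lt(rho, 0)
  expect_true(all(bins$mean_r2[ok] >= 0 & bins$mean_r2[ok] <= 1))
})

test_that("Sved's f closed forms and domain", {
  expect_equal(sved_f(0.5), 1.5)
  expect_equal(sved_f(0.1), 0.1 * 0.95 / 0.81)
  expect_equal(sved_f(1e-6) / 1e-6, 1, tolerance = 1e-5)
  expect_error(sved_f(1.2), "recombination fraction")
})

test_that("closed-form N_e case: r2_adj = 0.25, alpha = 2, small c", {
  bins <- data.frame(lo_bp = 0, hi_bp = 2e5, representative_distance = 1e5,
                     mean_r2 = 0.25 + 1 / (2 * 50), n_pairs = 10L)
  traj <- ne_trajectory(bins, n_sample = 50, alpha = 2, cm_per_mb = 1)
  # c = 0.001; N = (4 f(c))^-1 (4 - 2) ~ 1/(2c) = 500
  expect_equal(traj$ne, 500, tolerance = 0.01)
  expect_equal(traj$t, round(1 / (2 * 0.001)))
})

test_that("N_T is monotone decreasing in alpha at fixed LD", {
  bins <- data.frame(lo_bp = 0, hi_bp = 2e6, representative_distance = 1e6,
                     mean_r2 = 0.15, n_pairs = 30L)
  ne_vals <- vapply(c(1, 2, 2.2), function(a)
    ne_trajectory(bins, n_sample = 50, alpha = a)$ne, numeric(1))
  expect_true(all(diff(ne_vals) < 0))
})

test_that("bins implying negative N_e are dropped with a warning", {
  bins <- data.frame(lo_bp = 0, hi_bp = 2e5, representative_distance = 1e5,
                     mean_r2 = c(0.9, 0.15), n_pairs = c(5L, 5L))
  bins$representative_distance <- c(1e5, 1e6)
  bins$lo_bp <- c(0, 2e5); bins$hi_bp <- c(2e5, 2e6)
  expect_warning(traj <- ne_trajectory(bins, n_sample = 50, alpha = 2.2),
                 "negative")
  expect_equal(nrow(traj), 1L)
})

test_that("a simulated expansion shows larger recent than ancient N_e", {
  wins <- 0
  for (seed in c(3, 11, 27)) {
    ds <- simulate_wright_fisher(
      data.frame(gens = c(150, 30), ne = c(40, 200)), 3e7, 1e-8,
      400, 50, seed = seed)
    bins <- ld_decay(ds, max_distance_bp = 4e6,
                     breaks = ne_bins_logspaced(5e4, 4e6, 10), min_maf = 0.05)
    traj <- suppressWarnings(ne_trajectory(bins, n_sample = 50, alpha = 2.2))
    traj <- traj[traj$n_pairs >= 20, ]
    recent <- traj$ne[traj$t <= 25]
    ancient <- traj$ne[traj$t >= 45]
    if (length(recent) > 0 && length(ancient) > 0 &&
        mean(recent) > mean(ancient)) wins <- wins + 1
  }
  expect_gte(wins, 2)
})
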