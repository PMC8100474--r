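test_that("D_A closed forms: identity, disjoint fixation, hand case", {
  x <- runif(50)
  expect_equal(nei_da_pair(x, x), 0)
  expect_equal(nei_da_pair(rep(1, 20), rep(0, 20)), 1)
  expect_equal(nei_da_pair(1, 0.5), 1 - sqrt(0.5))
})

test_that("loci undefined in either population are dropped from r", {
  x <- c(0.5, NA, 0.2)
  y <- c(0.5, 0.3, NA)
  expect_message(d <- nei_da_pair(x, y), "dropped")
  expect_equal(d, 0)  # only the identical locus survives
})

test_that("duplicated population gives near-zero D_A; matrix is invariant
           to sample order", {
  ds <- simulate_balding_nichols(2, 30, 800, 0.2, seed = 5)
  dup <- ds
  dup$samples$population[dup$samples$population == "pop2"] <- "pop1b"
  dup$samples$population[1:30] <- "pop1a"
  # split pop1 into two labels instead: rebuild cleanly
  ds2 <- ds
  ds2$samples$population <- c(rep("p1a", 15), rep("p1b", 15), rep("q", 30))
  d <- da_matrix(ds2)
  expect_lt(d["p1a", "p1b"], 0.02)
  expect_gt(d["p1a", "q"], d["p1a", "p1b"])
  perm <- sample(n_samples(ds2))
  d_perm <- da_matrix(subset_dataset(ds2, samples = perm))
  expect_equal(d[rownames(d_perm), colnames(d_perm)], d_perm, tolerance = 1e-12)
})

test_that("stronger drift gives larger D_A (monotonic over replicates)", {
  wins <- 0
  for (seed in 1:10) {
    lo <- simulate_balding_nichols(2, 25, 500, 0.05, seed = seed)
    hi <- simulate_balding_nichols(2, 25, 500, 0.30, seed = seed + 100)
    d_lo <- da_matrix(lo)[1, 2]
    d_hi <- da_matrix(hi)[1, 2]
    if (d_hi > d_lo) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("NJ reconstructs random additive trees exactly", {
  set.seed(77)
  for (i in 1:20) {
    case <- random_additive_case(sample(5:8, 1))
    tree <- neighbor_joining(case$d)
    got <- cophenetic(tree)[rownames(case$d), colnames(case$d)]
    expect_lt(max(abs(got - case$d)), 1e-9)
    expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(case$tree)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("three taxa give the closed-form star branch lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(d)
  lens <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(lens[["A"]], (3 + 4 - 5) / 2)
  expect_equal(lens[["B"]], (3 + 5 - 4) / 2)
  expect_equal(lens[["C"]], (4 + 5 - 3) / 2)
})

test_that("NJ agrees with the reference implementation on random matrices", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:7, 1)
    m <- matrix(runif(n * n, 0.1, 1), n)
    d <- (m + t(m)) / 2
    diag(d) <- 0
    dimnames(d) <- list(letters[1:n], letters[1:n])
    mine <- neighbor_joining(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
    expect_equal(sum(mine$edge.length), sum(ref$edge.length), tolerance = 1e-9)
  }
})

test_that("asymmetric or negative matrices are rejected", {
  d <- matrix(c(0, 1, 2, 0.5, 0, 1, 2, 1, 0), 3)
  expect_error(neighbor_joining(d), "symmetric")
  d2 <- matrix(c(0, -1, 1, -1, 0, 1, 1, 1, 0), 3)
  expect_error(neighbor_joining(d2), "non-negative")
})

test_that("deeply split clades earn high bootstrap support", {
  # two clades of two populations each; tiny within-clade, huge between
  ds <- simulate_balding_nichols(4, 25, 800, c(0.02, 0.02, 0.02, 0.02), seed = 55)
  g <- ds$genotypes
  # push pops 3-4 far away: flip a third of their loci
  rows <- ds$samples$population %in% c("pop3", "pop4")
  flip <- seq(1, n_snps(ds), by = 3)
  g[rows, flip] <- 2L - g[rows, flip]
  ds$genotypes <- g
  tr <- bootstrap_tree(ds, n_reps = 100, seed = 8)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_gte(max(sup, na.rm = TRUE), 95)
})

test_that("bootstrap supports are deterministic under a fixed seed and absent
           when n_reps = 0", {
  ds <- simulate_balding_nichols(4, 15, 300, 0.2, seed = 66)
  t1 <- bootstrap_tree(ds, n_reps = 50, seed = 4)
  t2 <- bootstrap_tree(ds, n_reps = 50, seed = 4)
  expect_identical(t1$node.label, t2$node.label)
  t0 <- bootstrap_tree(ds, n_reps = 0)
  expect_null(t0$node.label)
})

test_that("Newick output round-trips topology, lengths and supports", {
  ds <- simulate_balding_nichols(4, 15, 300, 0.25, seed = 91)
  tr <- bootstrap_tree(ds, n_reps = 20, seed = 2)
  path <- file.path(withr::local_tempdir(), "tree.nwk")
  write_newick(tr, path)
  txt <- readLines(path)
  expect_match(txt, "^\\(.*\\);$")
  back <- ape::read.tree(path)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(sum(back$edge.length), sum(tr$edge.length), tolerance = 1e-9)
  expect_equal(ape::dist.topo(back, tr), 0, ignore_attr = TRUE)
  expect_true(any(nzchar(back$node.label)))
})
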