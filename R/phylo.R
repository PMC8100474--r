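#' Nei's D_A distance between two allele-frequency profiles
#'
#' For biallelic loci with counted-allele frequencies `x` and `y` in two
#' populations, D_A = 1 - (1/r) * sum_j [sqrt(x_j y_j) +
#' sqrt((1-x_j)(1-y_j))], where r is the number of loci defined in both
#' populations (loci undefined in either are dropped from r).  Identical
#' profiles give 0; fixation for alternate alleles at every locus gives 1.
#'
#' @param x,y numeric vectors of per-locus counted-allele frequencies
#'   (NA = undefined locus).
#' @return D_A in [0, 1].
#' @export
nei_da_pair <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (!all(ok)) message(sum(!ok), " undefined loci dropped from D_A")
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0) stop("no loci defined in both populations")
  1 - mean(sqrt(x * y) + sqrt((1 - x) * (1 - y)))
}

#' Pairwise D_A matrix over populations
#'
#' @param ds a [genotype_dataset()].
#' @return symmetric matrix of Nei's D_A with zero diagonal, labelled by
#'   population.
#' @export
da_matrix <- function(ds) {
  validate_genotype_dataset(ds)
  pops <- populations(ds)
  freqs <- vapply(pops, function(p) pop_allele_freq(ds, p),
                  numeric(n_snps(ds)))
  K <- length(pops)
  d <- matrix(0, K, K, dimnames = list(pops, pops))
  for (i in seq_len(K - 1)) for (j in (i + 1):K)
    d[i, j] <- d[j, i] <- nei_da_pair(freqs[, i], freqs[, j])
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion.  Ties in the
#' minimal Q are broken by the lexicographically lowest label pair (internal
#' nodes carry the smallest leaf label of their clade), so the result is
#' fully deterministic.  Branch lengths can be slightly negative, as usual
#' for NJ; they are kept raw in the returned tree.
#'
#' @param d symmetric distance matrix with labels as dimnames, >= 3 taxa.
#' @return an unrooted `phylo` tree (ape) with branch lengths.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need >= 3 taxa")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distance matrix must be non-negative")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  nwk <- labels          # growing newick fragment per active node
  key <- labels          # tie-break label (smallest leaf label in clade)
  fmt <- function(z) formatC(z, digits = 17, format = "g")
  while (nrow(d) > 3) {
    m <- nrow(d)
    R <- rowSums(d)
    Q <- (m - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_keys <- apply(cand, 1, function(ij)
      paste(sort(c(key[ij[1]], key[ij[2]]), method = "radix"), collapse = "\r"))
    pick <- cand[order(pair_keys, method = "radix")[1], ]
    i <- pick[1]; j <- pick[2]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    new_key <- sort(c(key[i], key[j]), method = "radix")[1]
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    key <- c(key[keep], new_key)
    d <- d2
  }
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 nwk[1], fmt(l1), nwk[2], fmt(l2), nwk[3], fmt(l3))
  ape::read.tree(text = txt)
}

# canonical bipartition strings for the internal edges of an unrooted tree:
# each split is represented by the side NOT containing the reference tip,
# as a sorted, collapsed label string; trivial splits are excluded
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  parts <- ape::prop.part(tree)
  out <- character(0)
  for (s in parts) {
    side <- tree$tip.label[s]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) <= 1 || length(side) >= length(tips) - 1) next
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Bootstrap-supported NJ tree of populations
#'
#' Point estimate: NJ on the D_A matrix of the full data.  Supports: loci
#' are resampled with replacement `n_reps` times, the D_A + NJ pipeline is
#' rerun, and each internal edge of the point tree is labelled with the
#' percentage of replicate trees containing its bipartition.
#'
#' @param ds a [genotype_dataset()] with >= 3 populations.
#' @param n_reps bootstrap replicates (0 = point tree, no supports).
#' @param seed integer RNG seed.
#' @return a `phylo` tree; internal `node.label` holds integer percent
#'   supports (empty at the unrooted basal node and when `n_reps = 0`).
#' @export
bootstrap_tree <- function(ds, n_reps = 1000, seed = 1) {
  validate_genotype_dataset(ds)
  if (length(populations(ds)) < 3) stop("need >= 3 populations")
  point <- neighbor_joining(da_matrix(ds))
  if (n_reps == 0) return(point)
  set.seed(seed)
  m <- n_snps(ds)
  counts <- stats::setNames(integer(0), character(0))
  target <- tree_bipartitions(point)
  counts <- stats::setNames(rep(0L, length(target)), target)
  for (b in seq_len(n_reps)) {
    idx <- sample.int(m, m, replace = TRUE)
    rep_tree <- neighbor_joining(da_matrix(subset_dataset(ds, snps = idx)))
    hit <- intersect(tree_bipartitions(rep_tree), target)
    counts[hit] <- counts[hit] + 1L
  }
  support <- round(100 * counts / n_reps)
  # attach support to each internal node via its bipartition
  parts <- ape::prop.part(point)
  ref <- sort(point$tip.label)[1]
  lab <- character(point$Nnode)
  for (k in seq_along(parts)) {
    side <- point$tip.label[parts[[k]]]
    if (ref %in% side) side <- setdiff(point$tip.label, side)
    keystr <- paste(sort(side), collapse = "|")
    lab[k] <- if (keystr %in% names(support)) as.character(support[[keystr]]) else ""
  }
  point$node.label <- lab
  point
}

#' Write a tree as Newick
#'
#' Branch lengths at full precision (round-trips through [ape::read.tree()]
#' far below 1e-9); internal node labels (bootstrap supports) are kept.
#'
#' @param tree a `phylo`.
#' @param path output file.
#' @param clamp_negative clamp negative NJ branch lengths to 0 for display.
#' @export
write_newick <- function(tree, path, clamp_negative = FALSE) {
  if (clamp_negative) tree$edge.length <- pmax(tree$edge.length, 0)
  ape::write.tree(tree, file = path, digits = 15)
  invisible(NULL)
}
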