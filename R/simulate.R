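#' Simulate structured populations under the Balding-Nichols model
#'
#' Per locus an ancestral frequency p is drawn uniformly from
#' `ancestral_maf_range`; each population's frequency is drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), which has mean p and variance F p (1-p), so
#' `fst` is the exact target differentiation the Weir-Cockerham estimator
#' should recover.  Genotypes are Binomial(2, p_k) within each population
#' (Hardy-Weinberg within populations).
#'
#' @param n_pops number of populations.
#' @param n_per_pop diploid individuals per population (scalar or vector).
#' @param n_loci number of biallelic loci.
#' @param fst target differentiation, scalar or per-population vector, in (0,1).
#' @param ancestral_maf_range interval for the ancestral frequency draw.
#' @param seed integer RNG seed; the dataset is bit-reproducible given it.
#' @return a [genotype_dataset()] with populations labelled `pop1..popK`,
#'   all loci on one synthetic chromosome at 10 kb spacing.
#' @export
simulate_balding_nichols <- function(n_pops, n_per_pop, n_loci, fst,
                                     ancestral_maf_range = c(0.1, 0.9),
                                     seed = 1) {
  stopifnot(all(fst > 0), all(fst < 1), all(n_per_pop >= 2))
  n_per_pop <- rep_len(n_per_pop, n_pops)
  fst <- rep_len(fst, n_pops)
  set.seed(seed)
  p_anc <- stats::runif(n_loci, ancestral_maf_range[1], ancestral_maf_range[2])
  g <- matrix(NA_integer_, sum(n_per_pop), n_loci)
  row0 <- 0
  for (k in seq_len(n_pops)) {
    Fk <- fst[k]
    pk <- stats::rbeta(n_loci, p_anc * (1 - Fk) / Fk,
                       (1 - p_anc) * (1 - Fk) / Fk)
    # rbeta can underflow to exactly 0/1 for tiny F; clamp to keep loci usable
    pk <- pmin(pmax(pk, 1e-12), 1 - 1e-12)
    nk <- n_per_pop[k]
    g[row0 + seq_len(nk), ] <- matrix(
      stats::rbinom(nk * n_loci, 2, rep(pk, each = nk)), nk, n_loci)
    row0 <- row0 + nk
  }
  build_sim_dataset(g, rep(paste0("pop", seq_len(n_pops)), n_per_pop))
}

#' Simulate genotypes of admixed individuals with known ancestry
#'
#' Each of an individual's two allele copies at a locus picks its source
#' population from the individual's ancestry vector `Q[i, ]`, then draws the
#' allele from that source's frequency `F[k, j]`; the dosage is the sum of
#' the two copies.
#'
#' @param Q individuals x K matrix of ancestry fractions (rows sum to 1).
#' @param F_mat K x loci matrix of source allele frequencies in [0, 1].
#' @param seed integer RNG seed.
#' @return a [genotype_dataset()]; population labels record the majority
#'   ancestry component (`src1..srcK`).
#' @export
simulate_admixed <- function(Q, F_mat, seed = 1) {
  Q <- as.matrix(Q); F_mat <- as.matrix(F_mat)
  stopifnot(ncol(Q) == nrow(F_mat),
            max(abs(rowSums(Q) - 1)) < 1e-8,
            all(F_mat >= 0), all(F_mat <= 1))
  n <- nrow(Q); m <- ncol(F_mat); K <- ncol(Q)
  set.seed(seed)
  g <- matrix(0L, n, m)
  for (copy in 1:2) {
    # source of each (individual, locus) allele copy
    src <- matrix(apply(Q, 1, function(q) sample.int(K, m, replace = TRUE, prob = q)),
                  n, m, byrow = TRUE)
    pf <- matrix(F_mat[cbind(as.vector(src), rep(seq_len(m), each = n))], n, m)
    g <- g + (matrix(stats::runif(n * m), n, m) < pf)
  }
  storage.mode(g) <- "integer"
  build_sim_dataset(g, paste0("src", max.col(Q, ties.method = "first")))
}

#' Inject inbreeding into a dataset
#'
#' With probability `f_target`, an individual's genotype at a locus is
#' replaced by a homozygote drawn with allele probability equal to that
#' population's allele frequency -- i.e. the two allele copies become fully
#' correlated -- so the expected within-population inbreeding coefficient is
#' `f_target`.  Expected allele frequencies are unchanged.
#'
#' @param ds a [genotype_dataset()].
#' @param f_target inbreeding coefficient in [0, 1).
#' @param seed integer RNG seed.
#' @return a modified [genotype_dataset()].
#' @export
inject_inbreeding <- function(ds, f_target, seed = 1) {
  validate_genotype_dataset(ds)
  stopifnot(f_target >= 0, f_target < 1)
  if (f_target == 0) return(ds)
  set.seed(seed)
  g <- ds$genotypes
  for (popname in populations(ds)) {
    rows <- pop_rows(ds, popname)
    sub <- g[rows, , drop = FALSE]
    p <- colMeans(sub, na.rm = TRUE) / 2
    hit <- matrix(stats::runif(length(sub)) < f_target, nrow(sub))
    hom <- matrix(2L * (stats::runif(length(sub)) <
                          rep(p, each = nrow(sub))), nrow(sub))
    sub[hit & !is.na(sub)] <- hom[hit & !is.na(sub)]
    g[rows, ] <- sub
  }
  storage.mode(g) <- "integer"
  out <- ds
  out$genotypes <- g
  out
}

#' Forward Wright-Fisher simulation with recombination
#'
#' Evolves 2N haplotypes per generation under random mating with Poisson
#' crossovers, following a step trajectory of effective sizes, then samples
#' diploids.  Loci monomorphic in the final sample are dropped (with a
#' message), so the returned map is an ascertained polymorphic panel -- the
#' situation an LD-based N_e estimator faces with array data.
#'
#' @param ne_trajectory data.frame with columns `gens` (span length, most
#'   ancient first) and `ne`; e.g. `data.frame(gens = 300, ne = 100)` for a
#'   constant size.
#' @param chrom_length_bp chromosome length in bp.
#' @param recomb_rate per-bp per-generation crossover rate (1e-8 = 1 cM/Mb).
#' @param n_loci loci, uniformly placed then jittered, initial frequencies
#'   uniform in (0.1, 0.9).
#' @param n_sample diploid sample size returned.
#' @param mu optional symmetric per-site flip rate per generation (default 0).
#' @param seed integer RNG seed.
#' @return a [genotype_dataset()] with a single population `"wf"`.
#' @export
simulate_wright_fisher <- function(ne_trajectory, chrom_length_bp, recomb_rate,
                                   n_loci, n_sample, mu = 0, seed = 1) {
  stopifnot(all(ne_trajectory$ne >= 2), recomb_rate >= 0,
            n_sample >= 2)
  set.seed(seed)
  pos <- sort(sample.int(chrom_length_bp, n_loci))
  p0 <- stats::runif(n_loci, 0.1, 0.9)
  ne0 <- ne_trajectory$ne[1]
  hap <- matrix(stats::runif(2 * ne0 * n_loci) < rep(p0, each = 2 * ne0),
                2 * ne0, n_loci)
  storage.mode(hap) <- "integer"
  map_len <- chrom_length_bp * recomb_rate  # Morgans
  for (epoch in seq_len(nrow(ne_trajectory))) {
    ne <- ne_trajectory$ne[epoch]
    for (gen in seq_len(ne_trajectory$gens[epoch])) {
      hap <- wf_next_generation(hap, ne, pos, map_len, chrom_length_bp)
      if (mu > 0) {
        flip <- matrix(stats::runif(length(hap)) < mu, nrow(hap))
        hap[flip] <- 1L - hap[flip]
      }
    }
  }
  ne_last <- nrow(hap) / 2
  take <- sample.int(ne_last, min(n_sample, ne_last))
  g <- hap[2 * take - 1, , drop = FALSE] + hap[2 * take, , drop = FALSE]
  freq <- colMeans(g) / 2
  poly <- freq > 0 & freq < 1
  if (any(!poly))
    message(sum(!poly), " monomorphic loci dropped from the final sample")
  g <- g[, poly, drop = FALSE]
  storage.mode(g) <- "integer"
  build_sim_dataset(g, rep("wf", nrow(g)), pos = pos[poly])
}

# one Wright-Fisher generation: 2*ne gametes from ne random parents
wf_next_generation <- function(hap, ne, pos, map_len, chrom_length_bp) {
  n_parents <- nrow(hap) / 2
  m <- ncol(hap)
  out <- matrix(0L, 2 * ne, m)
  parents <- sample.int(n_parents, 2 * ne, replace = TRUE)
  n_cross <- stats::rpois(2 * ne, map_len)
  start_hap <- sample.int(2, 2 * ne, replace = TRUE)
  for (i in seq_len(2 * ne)) {
    h1 <- hap[2 * parents[i] - 1, ]
    h2 <- hap[2 * parents[i], ]
    if (n_cross[i] == 0) {
      out[i, ] <- if (start_hap[i] == 1) h1 else h2
    } else {
      cuts <- sort(stats::runif(n_cross[i], 0, chrom_length_bp))
      seg <- findInterval(pos, cuts)  # segment index per locus
      use1 <- (seg + start_hap[i]) %% 2 == 1
      out[i, ] <- ifelse(use1, h1, h2)
    }
  }
  out
}

build_sim_dataset <- function(g, pop_labels, pos = NULL) {
  n <- nrow(g); m <- ncol(g)
  if (is.null(pos)) pos <- seq_len(m) * 10000L
  snps <- data.frame(id = sprintf("snp%d", seq_len(m)),
                     chrom = rep(1L, m), pos = as.integer(pos),
                     allele_a = rep("A", m), allele_b = rep("B", m),
                     stringsAsFactors = FALSE)
  samples <- data.frame(id = sprintf("ind%d", seq_len(n)),
                        population = pop_labels, stringsAsFactors = FALSE)
  genotype_dataset(g, snps, samples)
}
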