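#' Allele-frequency PCA of genotypes
#'
#' Each SNP column is mean-centred and scaled by sqrt(p(1-p)) with
#' p = (column mean)/2 (the drift-variance scaling standard for population
#' stratification analyses); missing calls are imputed to the column mean;
#' monomorphic SNPs are skipped.  Scores come from the SVD of the scaled
#' matrix; explained fractions are squared singular values over their total.
#'
#' @param ds a [genotype_dataset()].
#' @param k number of components, `< min(samples, SNPs)`.
#' @param scale use the sqrt(p(1-p)) scaling (TRUE) or centring only.
#' @return a `pca_result` list: `coordinates` (samples x k, rownames =
#'   sample ids), `explained` (length k, non-increasing fractions).
#' @export
pca_genotypes <- function(ds, k = 10, scale = TRUE) {
  validate_genotype_dataset(ds)
  g <- ds$genotypes
  if (k >= min(dim(g))) stop("k must be < min(samples, SNPs)")
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  X <- sweep(g, 2, 2 * p)
  X[is.na(X)] <- 0  # mean imputation after centring
  if (scale) X <- sweep(X, 2, sqrt(p * (1 - p)), "/")
  s <- svd(X, nu = k, nv = 0)
  scores <- s$u %*% diag(s$d[seq_len(k)], k)
  rownames(scores) <- ds$samples$id
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(coordinates = scores,
                 explained = s$d[seq_len(k)]^2 / sum(s$d^2)),
            class = "pca_result")
}

#' PCA on population allele frequencies
#'
#' The population-level variant: rows are populations, entries are
#' per-population counted-allele frequencies; useful when breed
#' relationships rather than individual placement are of interest.
#'
#' @param ds a [genotype_dataset()].
#' @param k number of components, `< number of populations`.
#' @return a `pca_result` (rows = populations).
#' @export
pca_populations <- function(ds, k = 2) {
  pops <- populations(ds)
  if (k >= length(pops)) stop("k must be < number of populations")
  fr <- t(vapply(pops, function(p) pop_allele_freq(ds, p), numeric(n_snps(ds))))
  ok <- colSums(is.na(fr)) == 0
  X <- sweep(fr[, ok, drop = FALSE], 2, colMeans(fr[, ok, drop = FALSE]))
  s <- svd(X, nu = k, nv = 0)
  scores <- s$u %*% diag(s$d[seq_len(k)], k)
  rownames(scores) <- pops
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(coordinates = scores,
                 explained = s$d[seq_len(k)]^2 / sum(s$d^2)),
            class = "pca_result")
}

#' Model-based admixture estimation by EM
#'
#' Maximizes the binomial admixture log-likelihood
#' sum_ij [ g_ij log(sum_k q_ik f_kj) + (2 - g_ij) log(sum_k q_ik (1 - f_kj)) ]
#' over ancestry fractions Q (rows sum to 1) and cluster allele frequencies
#' F, by plain EM from a seeded random start.  Missing genotype entries are
#' skipped in the likelihood.  F is clipped to [1e-6, 1 - 1e-6] each step
#' for numerical stability; Q rows are renormalized to machine precision.
#' The log-likelihood trace is non-decreasing (an EM guarantee, asserted in
#' the test-suite).
#'
#' @param ds a [genotype_dataset()].
#' @param K number of ancestral clusters (1 <= K <= samples).
#' @param seed integer RNG seed for the random start.
#' @param tol stop when the log-likelihood gain drops below this.
#' @param max_iter iteration cap.
#' @return an `admixture_fit` list: `K`, `Q` (samples x K), `F` (K x SNPs),
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`, `seed`, `tol`.
#' @export
admixture_em <- function(ds, K, seed = 1, tol = 1e-6, max_iter = 2000) {
  validate_genotype_dataset(ds)
  if (K < 1) stop("K must be >= 1")
  if (K > n_samples(ds)) stop("K exceeds the number of samples")
  G <- ds$genotypes
  fit <- admixture_em_matrix(G, K, seed = seed, tol = tol, max_iter = max_iter)
  rownames(fit$Q) <- ds$samples$id
  colnames(fit$F) <- ds$snps$id
  fit
}

# core EM on a raw dosage matrix (used by cv_error on masked copies)
admixture_em_matrix <- function(G, K, seed = 1, tol = 1e-6, max_iter = 2000) {
  n <- nrow(G); m <- ncol(G)
  obs <- !is.na(G)
  G0 <- G; G0[!obs] <- 0L
  Ga <- G0                    # counted-allele copies
  Gb <- (2L - G0) * obs       # other-allele copies (0 where missing)
  n_calls <- rowSums(obs)
  set.seed(seed)
  eps <- 1e-6
  pooled <- colSums(Ga) / pmax(1, 2 * colSums(obs))
  F_mat <- matrix(pmin(pmax(rep(pooled, each = K) +
                              stats::runif(K * m, -0.1, 0.1), eps), 1 - eps), K, m)
  Q <- matrix(stats::rgamma(n * K, 1), n, K)
  Q <- Q / rowSums(Q)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    PA <- Q %*% F_mat
    PB <- 1 - PA
    ll <- sum(Ga * log(PA) + Gb * log(PB))
    trace <- c(trace, ll)
    if (is.finite(ll) && ll - ll_old < tol && it > 1) { converged <- TRUE; break }
    ll_old <- ll
    GA <- Ga / PA
    GB <- Gb / PB
    Qn <- Q * (GA %*% t(F_mat) + GB %*% t(1 - F_mat))
    Q <- Qn / (2 * pmax(1, n_calls))
    Q <- Q / rowSums(Q)
    f_num <- F_mat * (t(Q) %*% GA)
    f_den <- f_num + (1 - F_mat) * (t(Q) %*% GB)
    F_mat <- pmin(pmax(f_num / f_den, eps), 1 - eps)
  }
  structure(list(K = K, Q = Q, F = F_mat, loglik = trace[length(trace)],
                 loglik_trace = trace, n_iter = length(trace),
                 converged = converged, seed = seed, tol = tol),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture fit: K = %d, loglik = %.2f after %d EM iterations (%s)\n",
              x$K, x$loglik, x$n_iter,
              if (x$converged) "converged" else "iteration cap"))
  invisible(x)
}

#' Cross-validation error for choosing K
#'
#' Masks a random fold of the non-missing genotype *entries* (not whole
#' individuals), refits the admixture model on the remainder, and scores the
#' masked entries by squared deviation between the observed dosage and the
#' model prediction 2 * sum_k q_ik f_kj; the fold errors are averaged.  The
#' K minimizing this error is the supported number of clusters.
#'
#' @param ds a [genotype_dataset()].
#' @param K number of clusters to evaluate.
#' @param folds number of CV folds (>= 2).
#' @param seed integer RNG seed (drives both masking and EM starts).
#' @param tol,max_iter EM controls for the fold fits.
#' @return mean squared prediction error on masked entries.
#' @export
cv_error <- function(ds, K, folds = 5, seed = 1, tol = 1e-4, max_iter = 300) {
  validate_genotype_dataset(ds)
  if (folds < 2) stop("folds must be >= 2")
  G <- ds$genotypes
  idx <- which(!is.na(G))
  if (length(idx) == 0) {
    warning("no observed entries to mask; CV error 0 by convention")
    return(0)
  }
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), length(idx)))
  errs <- numeric(folds)
  for (fd in seq_len(folds)) {
    mask <- idx[fold_of == fd]
    Gtrain <- G
    Gtrain[mask] <- NA_integer_
    fit <- admixture_em_matrix(Gtrain, K, seed = seed + fd,
                               tol = tol, max_iter = max_iter)
    pred <- 2 * (fit$Q %*% fit$F)
    errs[fd] <- mean((G[mask] - pred[mask])^2)
  }
  mean(errs)
}

#' Align cluster labels between two Q matrices
#'
#' Admixture clusters are identifiable only up to permutation; this finds
#' the column permutation of `Q_hat` minimizing the mean absolute difference
#' to `Q_ref` by exhaustive search (fine for the small K used here).
#'
#' @param Q_hat,Q_ref samples x K ancestry matrices.
#' @return list: `Q` (permuted `Q_hat`), `perm`, `mae`.
#' @export
match_clusters <- function(Q_hat, Q_ref) {
  K <- ncol(Q_ref)
  stopifnot(ncol(Q_hat) == K, K <= 8)
  perms <- all_permutations(K)
  best <- NULL; best_mae <- Inf
  for (i in seq_len(nrow(perms))) {
    mae <- mean(abs(Q_hat[, perms[i, ], drop = FALSE] - Q_ref))
    if (mae < best_mae) { best_mae <- mae; best <- perms[i, ] }
  }
  list(Q = Q_hat[, best, drop = FALSE], perm = best, mae = best_mae)
}

all_permutations <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(K - 1)
  do.call(rbind, lapply(seq_len(K), function(pos)
    t(apply(sub, 1, function(p) append(p, K, after = pos - 1)))))
}
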