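#' Default run configuration
#'
#' Returns the full configuration list for [run_all()], with every stage
#' enabled and the package defaults filled in; override fields as needed.
#'
#' @param prefix input PLINK prefix (ignored if `dataset` is passed to
#'   [run_all()]).
#' @param dialect PLINK dialect of the input.
#' @param out_dir output directory.
#' @param seed master seed; each stochastic stage derives its own seed from
#'   it so stages stay reproducible individually.
#' @return a named configuration list.
#' @export
default_config <- function(prefix = NULL, dialect = "plink-binary",
                           out_dir = "herdchar_out", seed = 1) {
  list(
    prefix = prefix, dialect = dialect, out_dir = out_dir, seed = seed,
    stages = c("qc", "diversity", "fstats", "amova", "tree", "pca",
               "admixture", "ld", "ne"),
    qc = list(snp_call_rate = 0.95, sample_call_rate = 0.95,
              prune_window = 50, prune_step = 5, prune_r2 = 0.2),
    fstats = list(n_boot = 200, n_perm = 99),
    amova = list(n_perm = 99),
    tree = list(n_boot = 100),
    pca = list(k = 5),
    admixture = list(K_values = 2:4, folds = 5, tol = 1e-4, max_iter = 300),
    ld = list(population = NULL, max_distance_bp = 1e6, method = "em"),
    ne = list(alpha = 2.2, cm_per_mb = 1, lo_bp = 1e4, hi_bp = 4e6, n_bins = 20)
  )
}

#' Run the full characterization pipeline
#'
#' Executes, in fixed order: QC + LD pruning, diversity summaries,
#' Weir-Cockerham F-statistics (global and pairwise), AMOVA, D_A + NJ tree
#' with bootstrap, PCA, admixture with CV over a K range, binned LD decay
#' and the LD-based N_e trajectory.  Every stage writes a plain-text
#' artifact into `out_dir` and the run closes with a machine-readable
#' `summary.json` plus a log of per-stage parameters.  All randomness is
#' seeded from `config$seed`, so re-running the same configuration
#' reproduces identical outputs.
#'
#' @param config a list as from [default_config()].
#' @param dataset optional [genotype_dataset()]; if `NULL`, read from
#'   `config$prefix`.
#' @return invisibly, the output directory path.
#' @export
run_all <- function(config, dataset = NULL) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  cat(sprintf("herdchar run, seed %d\n", config$seed), file = log_path)
  logit <- function(...) cat(sprintf(...), file = log_path, append = TRUE)
  ds <- if (is.null(dataset)) read_genotypes(config$prefix, config$dialect) else dataset
  logit("input: %d samples x %d SNPs, %d populations\n",
        n_samples(ds), n_snps(ds), length(populations(ds)))
  stages <- config$stages
  summary <- list(seed = config$seed, stages = stages)

  if ("qc" %in% stages) {
    qc <- qc_filter(ds, config$qc$snp_call_rate, config$qc$sample_call_rate)
    ds <- qc$dataset
    kept <- ld_prune(ds, config$qc$prune_window, config$qc$prune_step,
                     config$qc$prune_r2)
    ds <- subset_dataset(ds, snps = kept)
    rep <- qc$report
    qc_out <- list(snps_removed = rep$snps_removed, snps_kept = rep$snps_kept,
                   samples_removed = rep$samples_removed,
                   samples_kept = rep$samples_kept,
                   snps_after_prune = length(kept))
    jsonlite::write_json(qc_out, file.path(out, "qc_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    summary$qc <- qc_out
    logit("qc: %d SNPs after call-rate filter, %d after pruning\n",
          rep$snps_kept, length(kept))
  }
  if ("diversity" %in% stages) {
    div <- diversity_summary(ds)
    utils::write.table(div, file.path(out, "diversity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$diversity <- div
    logit("diversity: %d populations summarised\n", nrow(div))
  }
  if ("fstats" %in% stages) {
    fs <- global_fstats(ds, n_boot = config$fstats$n_boot,
                        n_perm = config$fstats$n_perm, seed = config$seed)
    fs_out <- list(fst = fs$fst, fis = fs$fis, fit = fs$fit,
                   ci = if (!is.null(fs$ci)) as.data.frame(fs$ci),
                   p_value = as.list(fs$p_value))
    jsonlite::write_json(fs_out, file.path(out, "fstats.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    pw <- pairwise_fst(ds)
    utils::write.table(round(pw, 6), file.path(out, "pairwise_fst.tsv"),
                       sep = "\t", quote = FALSE)
    summary$fstats <- list(fst = fs$fst, fis = fs$fis, fit = fs$fit)
    logit("fstats: F_ST %.4f F_IS %.4f F_IT %.4f\n", fs$fst, fs$fis, fs$fit)
  }
  if ("amova" %in% stages) {
    am <- amova_three_level(ds, n_perm = config$amova$n_perm, seed = config$seed)
    tab <- data.frame(level = names(am$sigma2), df = am$df, SS = am$SS,
                      sigma2 = am$sigma2, percent = am$percents)
    if (!is.null(am$p_values)) tab$p <- am$p_values
    utils::write.table(tab, file.path(out, "amova.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$amova <- as.list(am$percents)
    logit("amova: %.2f%% / %.2f%% / %.2f%%\n", am$percents[1], am$percents[2],
          am$percents[3])
  }
  if ("tree" %in% stages && length(populations(ds)) >= 3) {
    tr <- bootstrap_tree(ds, n_reps = config$tree$n_boot, seed = config$seed)
    write_newick(tr, file.path(out, "tree.nwk"))
    utils::write.table(round(da_matrix(ds), 6), file.path(out, "da_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    summary$tree <- ape::write.tree(tr)
    logit("tree: %d tips, %d bootstrap replicates\n",
          length(tr$tip.label), config$tree$n_boot)
  }
  if ("pca" %in% stages) {
    pc <- pca_genotypes(ds, k = config$pca$k)
    tab <- data.frame(id = rownames(pc$coordinates),
                      population = ds$samples$population, pc$coordinates)
    utils::write.table(tab, file.path(out, "pca.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$pca_explained <- pc$explained
    logit("pca: first %d PCs explain %.1f%%\n", config$pca$k,
          100 * sum(pc$explained))
  }
  if ("admixture" %in% stages) {
    cvs <- vapply(config$admixture$K_values, function(K)
      cv_error(ds, K, folds = config$admixture$folds, seed = config$seed,
               tol = config$admixture$tol,
               max_iter = config$admixture$max_iter), numeric(1))
    cv_tab <- data.frame(K = config$admixture$K_values, cv_error = cvs)
    utils::write.table(cv_tab, file.path(out, "cv_error.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    K_best <- config$admixture$K_values[which.min(cvs)]
    fit <- admixture_em(ds, K_best, seed = config$seed,
                        tol = config$admixture$tol,
                        max_iter = config$admixture$max_iter)
    qtab <- data.frame(id = rownames(fit$Q),
                       population = ds$samples$population, round(fit$Q, 5))
    utils::write.table(qtab, file.path(out, "admixture_Q.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$admixture <- list(K_best = K_best, cv = cv_tab)
    logit("admixture: best K = %d by CV\n", K_best)
  }
  if ("ld" %in% stages) {
    bins <- ld_decay(ds, population = config$ld$population,
                     max_distance_bp = config$ld$max_distance_bp,
                     method = config$ld$method)
    utils::write.table(bins, file.path(out, "ld_bins.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    summary$ld <- bins
    logit("ld: %d pairs binned\n", sum(bins$n_pairs))
  }
  if ("ne" %in% stages) {
    nb <- ld_decay(ds, population = config$ld$population,
                   max_distance_bp = config$ne$hi_bp,
                   breaks = ne_bins_logspaced(config$ne$lo_bp, config$ne$hi_bp,
                                              config$ne$n_bins),
                   method = config$ld$method)
    n_dip <- if (is.null(config$ld$population)) n_samples(ds)
    else length(pop_rows(ds, config$ld$population))
    traj <- tryCatch(
      ne_trajectory(nb, n_sample = n_dip, alpha = config$ne$alpha,
                    cm_per_mb = config$ne$cm_per_mb),
      error = function(e) { logit("ne: skipped (%s)\n", conditionMessage(e)); NULL })
    if (!is.null(traj)) {
      utils::write.table(traj, file.path(out, "ne.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      summary$ne <- traj
      logit("ne: %d horizons estimated\n", nrow(traj))
    }
  }
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)
  invisible(out)
}
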