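#' Full PU-learning confidence pipeline
#'
#' Runs the complete procedure on a PU dataset: spy-fold scoring of the
#' actual labels (R repeats), a label-permutation null (B permutations),
#' the upper-tailed z-test and Cliff's Delta for both EPR and MBS, and —
#' when ground truth is available — the U-set ROC-AUC from a dedicated
#' full-KP PU bagging run (no spies removed). All randomness derives from
#' the single master `seed`; rerunning with the same inputs reproduces
#' the report exactly.
#'
#' When `output_dir` is given, the intermediate artifacts are written as
#' plain files: `spy_scores.csv` (long format: repeat, sample_id,
#' spy_score), `spy_summary.csv` (repeat, epr, mbs), `null.csv`
#' (perm_index, epr, mbs), `uauc_scores.csv` (sample_id, score,
#' oob_count, truth if present), `report.json`, and `manifest.yaml`
#' recording every derived seed. The report's mu/mu0/sigma recompute
#' exactly from `spy_summary.csv` and `null.csv`.
#'
#' @param data a [pu_dataset()]; needs at least `k_folds` known positives.
#' @param k_folds spy folds K (default 5).
#' @param n_repeats spy repeats R on the actual labels (default 30).
#' @param n_permutations null permutations B (default 30).
#' @param n_repeats_per_permutation spy repeats inside each permutation
#'   (default 1).
#' @param n_bootstraps PU bagging rounds T (default 100).
#' @param epr_threshold EPR decision threshold (default 0.5).
#' @param classifier classifier function (default RBF-SVM,
#'   [classifier_svm_rbf()]).
#' @param scale_on_bag standardize features from in-bag rows (default
#'   `TRUE`).
#' @param seed master seed.
#' @param output_dir optional directory for intermediate artifacts;
#'   created if needed.
#' @param verbose print progress messages (default `FALSE`).
#' @return an object of class `"pu_confidence"`: list with `report` (one
#'   data.frame row per metric: metric, mu, mu0, sigma, z, p_value,
#'   delta, delta_lo, delta_hi, magnitude, u_auc), plus the `spy`,
#'   `null`, and `bagging` result objects and the `seeds` manifest.
#' @examples
#' \donttest{
#' cfg <- synthetic_config(n_samples = 60, n_features = 20, class_sep = 2,
#'                         tn_proportion = 0.5, seed = 1)
#' pu <- relabel_pu(generate_synthetic(cfg), n_kp = 12, seed = 1)
#' fit <- pu_confidence(pu, n_repeats = 3, n_permutations = 5,
#'                      n_bootstraps = 20, seed = 1)
#' fit$report
#' }
#' @export
pu_confidence <- function(data, k_folds = 5, n_repeats = 30,
                          n_permutations = 30,
                          n_repeats_per_permutation = 1,
                          n_bootstraps = 100, epr_threshold = 0.5,
                          classifier = classifier_svm_rbf(),
                          scale_on_bag = TRUE, seed = 1,
                          output_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(data, "pu_dataset"))
  seeds <- list(master = seed,
                spy = derive_seed(seed, "pipeline", 1),
                null = derive_seed(seed, "pipeline", 2),
                bagging = derive_seed(seed, "pipeline", 3))

  if (verbose) message("Spy scoring of actual labels (R = ", n_repeats, ")")
  spy <- spy_fold_scores(data, k_folds = k_folds, n_repeats = n_repeats,
                         epr_threshold = epr_threshold,
                         n_bootstraps = n_bootstraps,
                         classifier = classifier,
                         scale_on_bag = scale_on_bag, seed = seeds$spy)

  if (verbose) message("Permutation null (B = ", n_permutations, ")")
  null <- build_null(data, n_permutations = n_permutations,
                     n_repeats_per_permutation = n_repeats_per_permutation,
                     k_folds = k_folds, epr_threshold = epr_threshold,
                     n_bootstraps = n_bootstraps, classifier = classifier,
                     scale_on_bag = scale_on_bag, seed = seeds$null)

  bagging <- NULL
  auc <- NA_real_
  if (!is.null(data$truth_labels)) {
    u_idx <- which(data$pu_labels == 0L)
    u_truth <- data$truth_labels[u_idx]
    if (length(unique(u_truth)) == 2L) {
      if (verbose) message("Full-KP PU bagging for U-AUC (T = ",
                           n_bootstraps, ")")
      bagging <- pu_bagging_scores(data, n_bootstraps = n_bootstraps,
                                   classifier = classifier,
                                   scale_on_bag = scale_on_bag,
                                   seed = seeds$bagging)
      auc <- u_auc(bagging$scores, u_truth)
    } else {
      warning("ground truth has a single class among U; skipping U-AUC")
    }
  }

  one_metric <- function(metric, actual, null_draws) {
    zt <- z_test(actual, null_draws)
    cd <- cliffs_delta(actual, null_draws)
    data.frame(metric = metric, mu = zt$mu, mu0 = zt$mu0,
               sigma = zt$sigma, z = zt$z, p_value = zt$p_value,
               delta = cd$estimate, delta_lo = cd$ci_low,
               delta_hi = cd$ci_high, magnitude = cd$magnitude,
               u_auc = auc, stringsAsFactors = FALSE)
  }
  report <- rbind(one_metric("EPR", spy$epr_per_repeat, null$epr_null),
                  one_metric("MBS", spy$mbs_per_repeat, null$mbs_null))

  out <- structure(list(report = report, spy = spy, null = null,
                        bagging = bagging, seeds = seeds,
                        k_folds = k_folds, n_repeats = n_repeats,
                        n_permutations = n_permutations,
                        n_bootstraps = n_bootstraps),
                   class = "pu_confidence")
  if (!is.null(output_dir)) .write_artifacts(out, data, output_dir)
  out
}

.write_artifacts <- function(fit, data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ss <- fit$spy$spy_scores
  long <- data.frame(repeat_index = rep(seq_len(nrow(ss)), ncol(ss)),
                     sample_id = rep(colnames(ss), each = nrow(ss)),
                     spy_score = round(as.vector(ss), 6))
  write.csv(long[order(long$repeat_index, long$sample_id), ],
            file.path(dir, "spy_scores.csv"), row.names = FALSE)
  write.csv(data.frame(repeat_index = seq_len(fit$spy$n_repeats),
                       epr = round(fit$spy$epr_per_repeat, 6),
                       mbs = round(fit$spy$mbs_per_repeat, 6)),
            file.path(dir, "spy_summary.csv"), row.names = FALSE)
  write.csv(data.frame(perm_index = seq_len(fit$null$n_permutations),
                       epr = round(fit$null$epr_null, 6),
                       mbs = round(fit$null$mbs_null, 6)),
            file.path(dir, "null.csv"), row.names = FALSE)
  if (!is.null(fit$bagging)) {
    u_idx <- fit$bagging$u_indices
    df <- data.frame(sample_id = names(fit$bagging$scores),
                     score = round(unname(fit$bagging$scores), 6),
                     oob_count = unname(fit$bagging$oob_counts))
    if (!is.null(data$truth_labels))
      df$truth_label <- data$truth_labels[u_idx]
    write.csv(df, file.path(dir, "uauc_scores.csv"), row.names = FALSE)
  }
  jsonlite::write_json(fit$report, file.path(dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  yaml::write_yaml(list(seeds = fit$seeds,
                        k_folds = fit$k_folds,
                        n_repeats = fit$n_repeats,
                        n_permutations = fit$n_permutations,
                        n_bootstraps = fit$n_bootstraps,
                        perm_seeds = fit$null$perm_seeds),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @export
print.pu_confidence <- function(x, ...) {
  cat("PU confidence report (K =", x$k_folds, ", R =", x$n_repeats,
      ", B =", x$n_permutations, ", T =", x$n_bootstraps, ")\n\n")
  rep <- x$report
  for (i in seq_len(nrow(rep))) {
    r <- rep[i, ]
    cat(sprintf("  %s: mu = %.4f  mu0 = %.4f  sigma = %.4f  z = %.2f  p = %.3g\n",
                r$metric, r$mu, r$mu0, r$sigma, r$z, r$p_value))
    cat(sprintf("       Cliff's Delta = %.3f [%.3f, %.3f] (%s)\n",
                r$delta, r$delta_lo, r$delta_hi, r$magnitude))
  }
  if (!is.na(rep$u_auc[1]))
    cat(sprintf("\n  U-AUC vs ground truth: %.3f\n", rep$u_auc[1]))
  invisible(x)
}
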