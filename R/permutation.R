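#' Randomly reassign the positive labels
#'
#' Produces a dataset with identical features and ground truth but with
#' the known-positive labels moved to a uniformly random subset of all
#' samples of the same size. This is the elementary step of the
#' permutation null: under the permuted labeling the "positives" are an
#' arbitrary subset, so their spy scores estimate what the pipeline
#' reports when the positive label carries no information.
#'
#' @param data a [pu_dataset()].
#' @param seed integer seed for the draw.
#' @return a [pu_dataset()] with the same number of positive labels. Note
#'   the returned object drops the KP-implies-TP invariant on purpose:
#'   permuted positives may land on true negatives.
#' @export
permute_labels <- function(data, seed = 1) {
  stopifnot(inherits(data, "pu_dataset"))
  n <- nrow(data$features)
  n_kp <- sum(data$pu_labels == 1L)
  set.seed(seed)
  pu <- integer(n)
  pu[sample.int(n, n_kp)] <- 1L
  out <- data
  out$pu_labels <- pu
  out
}

#' Permutation null distribution of EPR and MBS
#'
#' For each of `n_permutations` label permutations, reruns the full spy
#' scoring procedure ([spy_fold_scores()]) on the permuted labeling and
#' records the (mean over `n_repeats_per_permutation` repeats of) EPR and
#' MBS as one null draw. Each permutation derives its own seed from the
#' master seed and its index, so draws are independent and the null is
#' reproducible regardless of execution order.
#'
#' @param data a [pu_dataset()] carrying the actual labels.
#' @param n_permutations number of permutations B (default 30; the method
#'   is stable across 30/100/500).
#' @param n_repeats_per_permutation spy repeats per permutation (default
#'   1: one k-fold spy pass per null draw).
#' @inheritParams spy_fold_scores
#' @return an object of class `"pu_null"`: list with `epr_null` and
#'   `mbs_null` (length B), `perm_seeds` (audit trail of per-permutation
#'   seeds), and the configuration fields.
#' @export
build_null <- function(data, n_permutations = 30,
                       n_repeats_per_permutation = 1,
                       k_folds = 5, epr_threshold = 0.5,
                       n_bootstraps = 100,
                       classifier = classifier_svm_rbf(),
                       scale_on_bag = TRUE, seed = 1) {
  stopifnot(inherits(data, "pu_dataset"))
  if (n_permutations < 2)
    stop("n_permutations must be >= 2 (null SD uses n - 1 degrees of freedom)")
  epr_null <- mbs_null <- numeric(n_permutations)
  perm_seeds <- integer(n_permutations)
  for (b in seq_len(n_permutations)) {
    perm_seeds[b] <- derive_seed(seed, "permutation", b)
    permuted <- permute_labels(data, perm_seeds[b])
    sp <- tryCatch(
      spy_fold_scores(permuted, k_folds = k_folds,
                      n_repeats = n_repeats_per_permutation,
                      epr_threshold = epr_threshold,
                      n_bootstraps = n_bootstraps,
                      classifier = classifier,
                      scale_on_bag = scale_on_bag,
                      seed = derive_seed(seed, "spy", b)),
      error = function(e)
        stop("permutation ", b, " (seed ", perm_seeds[b],
             ") failed: ", conditionMessage(e), call. = FALSE))
    epr_null[b] <- mean(sp$epr_per_repeat)
    mbs_null[b] <- mean(sp$mbs_per_repeat)
  }
  structure(list(epr_null = epr_null, mbs_null = mbs_null,
                 perm_seeds = perm_seeds,
                 n_permutations = n_permutations,
                 n_repeats_per_permutation = n_repeats_per_permutation,
                 k_folds = k_folds, n_bootstraps = n_bootstraps,
                 seed = seed),
            class = "pu_null")
}

#' @export
print.pu_null <- function(x, ...) {
  cat("Permutation null:", x$n_permutations, "label permutations\n")
  cat(sprintf("  EPR null: mean %.3f (sd %.3f)   MBS null: mean %.3f (sd %.3f)\n",
              mean(x$epr_null), stats::sd(x$epr_null),
              mean(x$mbs_null), stats::sd(x$mbs_null)))
  invisible(x)
}
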