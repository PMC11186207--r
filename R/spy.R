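#' Explicit positive recall
#'
#' Fraction of scores strictly exceeding the decision threshold: a spy
#' positive counts as "predicted positive" only when its bagging score
#' exceeds (not merely reaches) the threshold.
#'
#' @param scores numeric vector of bagging scores in \[0, 1\].
#' @param threshold decision threshold (default 0.5).
#' @return proportion in \[0, 1\].
#' @examples
#' epr(c(0.9, 0.6, 0.4))        # 2/3
#' epr(c(0.5, 0.7))             # 0.5 — a score at the threshold is not counted
#' @export
epr <- function(scores, threshold = 0.5) {
  if (length(scores) == 0L) stop("epr() requires at least one score")
  if (anyNA(scores)) stop("scores contain NA")
  mean(scores > threshold)
}

#' Mean bagging score
#'
#' Arithmetic mean of the class-1 bagging scores; threshold-free.
#'
#' @param scores numeric vector of bagging scores in \[0, 1\].
#' @return mean score in \[0, 1\].
#' @export
mbs <- function(scores) {
  if (length(scores) == 0L) stop("mbs() requires at least one score")
  if (anyNA(scores)) stop("scores contain NA")
  mean(scores)
}

# Random partition of idx into k folds whose sizes differ by at most one.
.make_folds <- function(idx, k, seed) {
  set.seed(seed)
  shuffled <- sample(idx)
  split(shuffled, rep(seq_len(k), length.out = length(shuffled)))
}

#' K-fold spy scoring of the known-positive set
#'
#' Scores the known positives themselves: per repeat, KP is randomly
#' partitioned into `k_folds` folds; each fold in turn is reassigned to
#' the unlabeled set as a "spy fold", PU bagging is run with the remaining
#' KP as positives and the expanded U set, and the spies' bagging scores
#' are recorded. The K folds' spy scores are pooled, giving one score per
#' KP sample per repeat, from which the repeat's explicit positive recall
#' ([epr()]) and mean bagging score ([mbs()]) are computed. Repeating with
#' `n_repeats` different fold splits characterizes the variance of both
#' metrics.
#'
#' @param data a [pu_dataset()].
#' @param k_folds number of spy folds K (default 5); requires at least K
#'   known positives.
#' @param n_repeats number of independent fold splits R (default 30).
#' @param epr_threshold decision threshold for [epr()] (default 0.5).
#' @param n_bootstraps bootstrap rounds per PU bagging run (default 100).
#' @param classifier classifier function (see [classifier_svm_rbf()]).
#' @param scale_on_bag passed to [pu_bagging_scores()].
#' @param seed integer master seed; fold splits and bagging runs draw
#'   derived seeds.
#' @param keep_u_scores if `TRUE`, also retain the bagging scores of the
#'   original (non-spy) U samples from every spy run, for diagnostics.
#'   These diagnostic scores are not used by any downstream statistic.
#' @return an object of class `"spy_result"`: list with `spy_scores`
#'   (R x |KP| matrix, columns named by KP sample id), `epr_per_repeat`,
#'   `mbs_per_repeat`, the configuration fields, and optionally
#'   `u_scores` (list of per-repeat score matrices).
#' @export
spy_fold_scores <- function(data, k_folds = 5, n_repeats = 30,
                            epr_threshold = 0.5, n_bootstraps = 100,
                            classifier = classifier_svm_rbf(),
                            scale_on_bag = TRUE, seed = 1,
                            keep_u_scores = FALSE) {
  stopifnot(inherits(data, "pu_dataset"), k_folds >= 2, n_repeats >= 1)
  if (epr_threshold <= 0 || epr_threshold >= 1)
    stop("epr_threshold must lie strictly between 0 and 1")
  kp_idx <- which(data$pu_labels == 1L)
  if (length(kp_idx) < k_folds)
    stop("spy scoring requires count(KP) >= k_folds: have ",
         length(kp_idx), " known positives for K = ", k_folds)

  kp_ids <- rownames(data$features)[kp_idx]
  spy_scores <- matrix(NA_real_, n_repeats, length(kp_idx),
                       dimnames = list(NULL, kp_ids))
  u_diag <- if (keep_u_scores) vector("list", n_repeats) else NULL

  for (r in seq_len(n_repeats)) {
    folds <- .make_folds(kp_idx, k_folds, derive_seed(seed, "fold", r))
    u_acc <- if (keep_u_scores) list() else NULL
    for (k in seq_along(folds)) {
      fold <- folds[[k]]
      # modify labels in place: permuted inputs legitimately place KP on
      # true negatives, so re-validation through pu_dataset() must not run
      spy_data <- data
      spy_data$pu_labels[fold] <- 0L
      res <- pu_bagging_scores(
        spy_data, n_bootstraps = n_bootstraps, classifier = classifier,
        scale_on_bag = scale_on_bag,
        seed = derive_seed(seed, "spy", (r - 1L) * k_folds + k),
        score_only = if (keep_u_scores) NULL else fold)
      fold_ids <- rownames(data$features)[fold]
      spy_scores[r, fold_ids] <- res$scores[fold_ids]
      if (keep_u_scores) u_acc[[k]] <- res$scores
    }
    if (keep_u_scores) u_diag[[r]] <- u_acc
  }

  structure(list(spy_scores = spy_scores,
                 epr_per_repeat = apply(spy_scores, 1, epr,
                                        threshold = epr_threshold),
                 mbs_per_repeat = apply(spy_scores, 1, mbs),
                 k_folds = k_folds, n_repeats = n_repeats,
                 epr_threshold = epr_threshold,
                 n_bootstraps = n_bootstraps, seed = seed,
                 u_scores = u_diag),
            class = "spy_result")
}

#' @export
print.spy_result <- function(x, ...) {
  cat("Spy-fold scoring:", ncol(x$spy_scores), "known positives, K =",
      x$k_folds, ", R =", x$n_repeats, "repeats\n")
  cat(sprintf("  EPR: mean %.3f (sd %.3f)   MBS: mean %.3f (sd %.3f)\n",
              mean(x$epr_per_repeat), stats::sd(x$epr_per_repeat),
              mean(x$mbs_per_repeat), stats::sd(x$mbs_per_repeat)))
  invisible(x)
}
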