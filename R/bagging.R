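#' RBF-kernel support-vector classifier contract
#'
#' Returns a classifier function with signature
#' `function(train_x, train_y, test_x)` returning hard 0/1 class
#' predictions for `test_x`. The default hyperparameters of
#' [e1071::svm()] are used deliberately: in the PU setting there are no
#' ground-truth labels to tune against, so an untuned radial-basis SVM is
#' the honest default. The fit is deterministic given its inputs. Any
#' function honouring this contract (both classes required in `train_y`,
#' deterministic output) can be passed wherever a `classifier` argument is
#' accepted — PU bagging is largely insensitive to the choice.
#'
#' @param ... further arguments passed to [e1071::svm()] (e.g. `cost`,
#'   `gamma`).
#' @return a classifier function.
#' @examples
#' clf <- classifier_svm_rbf()
#' tr <- rbind(matrix(rnorm(20, -3), 10), matrix(rnorm(20, 3), 10))
#' clf(tr, rep(0:1, each = 10), matrix(c(3, 3), 1))
#' @export
classifier_svm_rbf <- function(...) {
  function(train_x, train_y, test_x) {
    if (length(unique(train_y)) < 2L)
      stop("training labels contain a single class; cannot fit classifier")
    fit <- e1071::svm(train_x, factor(train_y, levels = c(0, 1)),
                      kernel = "radial", scale = FALSE, ...)
    as.integer(as.character(predict(fit, test_x)))
  }
}

# Standardization parameters from the in-bag rows only; constant features
# get unit divisor so OOB rows never divide by zero.
.bag_scaler <- function(train_x) {
  m <- colMeans(train_x)
  n <- nrow(train_x)
  s <- sqrt(colSums(sweep(train_x, 2, m)^2) / max(n - 1, 1))
  s[!is.finite(s) | s < .Machine$double.eps] <- 1
  list(center = m, scale = s)
}

.apply_scaler <- function(x, sc) {
  sweep(sweep(x, 2, sc$center), 2, sc$scale, "/")
}

#' Transductive PU bagging scores for the unlabeled set
#'
#' Implements PU bagging with out-of-bag (OOB) vote aggregation. In each
#' of `n_bootstraps` rounds, a number of unlabeled samples matching the
#' known-positive count is drawn with replacement from the U set and
#' temporarily labeled negative; a classifier is fitted on all known
#' positives (class 1) against the bag (class 0); every U sample left out
#' of the bag is predicted while "OOB". The score of a U sample is
#'
#' \deqn{\mathrm{score}_i = \frac{\#\{\text{rounds OOB and predicted 1}\}}
#'                               {\#\{\text{rounds OOB}\}}}
#'
#' i.e. the fraction of its OOB rounds in which it was voted class 1.
#' When `scale_on_bag` is `TRUE`, per-feature centering/scaling parameters
#' are computed from the in-bag training rows only and applied to the OOB
#' rows before prediction.
#'
#' A U sample that is never OOB across all rounds (essentially impossible
#' at the default 100 bootstraps) receives the neutral score 0.5 with a
#' warning rather than an error, so downstream ranking stays defined.
#'
#' @param data a [pu_dataset()].
#' @param n_bootstraps number of bootstrap rounds T (default 100).
#' @param classifier a classifier function honouring the
#'   [classifier_svm_rbf()] contract.
#' @param scale_on_bag standardize features using in-bag parameters
#'   (default `TRUE`).
#' @param seed integer master seed; round `t` uses the derived seed
#'   `derive_seed(seed, "bag", t)`.
#' @param score_only optional integer vector of sample indices (into the
#'   rows of `data$features`, all unlabeled) to restrict scoring to.
#'   Per-row predictions are independent, so restricting changes no
#'   reported score; it only skips prediction work for the other U
#'   samples.
#' @return an object of class `"pu_bagging_result"`: list with `scores`,
#'   `oob_counts`, `positive_votes` (all named by sample id, over the
#'   scored U samples), `u_indices`, `n_bootstraps`, `seed`.
#' @references Mordelet & Vert-style bagging for PU learning.
#' @export
pu_bagging_scores <- function(data, n_bootstraps = 100,
                              classifier = classifier_svm_rbf(),
                              scale_on_bag = TRUE, seed = 1,
                              score_only = NULL) {
  stopifnot(inherits(data, "pu_dataset"), n_bootstraps >= 1)
  p_idx <- which(data$pu_labels == 1L)
  u_idx <- which(data$pu_labels == 0L)
  if (length(p_idx) < 1L) stop("no known positives in the dataset")
  if (length(u_idx) < 1L) stop("no unlabeled samples in the dataset")
  if (is.null(score_only)) {
    scored <- u_idx
  } else {
    scored <- as.integer(score_only)
    if (!all(scored %in% u_idx))
      stop("score_only must index unlabeled samples")
  }

  x <- data$features
  n_scored <- length(scored)
  votes <- counts <- integer(n_scored)
  pos <- match(scored, u_idx)  # position of scored samples within U
  train_y <- c(rep(1L, length(p_idx)), rep(0L, length(p_idx)))

  for (t in seq_len(n_bootstraps)) {
    set.seed(derive_seed(seed, "bag", t))
    bag <- u_idx[sample.int(length(u_idx), length(p_idx), replace = TRUE)]
    in_bag <- unique(bag)
    oob_mask <- !(scored %in% in_bag)
    if (!any(oob_mask)) next
    train_x <- x[c(p_idx, bag), , drop = FALSE]
    test_x <- x[scored[oob_mask], , drop = FALSE]
    if (scale_on_bag) {
      sc <- .bag_scaler(train_x)
      train_x <- .apply_scaler(train_x, sc)
      test_x <- .apply_scaler(test_x, sc)
    }
    pred <- classifier(train_x, train_y, test_x)
    counts[oob_mask] <- counts[oob_mask] + 1L
    votes[oob_mask] <- votes[oob_mask] + as.integer(pred == 1L)
  }

  scores <- ifelse(counts > 0L, votes / pmax(counts, 1L), 0.5)
  if (any(counts == 0L))
    warning(sum(counts == 0L), " unlabeled sample(s) were never ",
            "out-of-bag; assigned neutral score 0.5")
  ids <- rownames(x)[scored]
  structure(list(scores = stats::setNames(scores, ids),
                 oob_counts = stats::setNames(counts, ids),
                 positive_votes = stats::setNames(votes, ids),
                 u_indices = scored,
                 n_bootstraps = n_bootstraps,
                 seed = seed),
            class = "pu_bagging_result")
}

#' @export
print.pu_bagging_result <- function(x, ...) {
  cat("PU bagging result:", length(x$scores), "unlabeled samples scored,",
      x$n_bootstraps, "bootstraps\n")
  cat("  score range: [", sprintf("%.3f", min(x$scores)), ",",
      sprintf("%.3f", max(x$scores)), "]  mean OOB count:",
      sprintf("%.1f", mean(x$oob_counts)), "\n")
  invisible(x)
}
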