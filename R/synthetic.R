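#' Configuration for the synthetic two-class generator
#'
#' Defines a labeled two-class dataset in which a controllable fraction of
#' features is informative, the remainder redundant (random linear
#' combinations of the informative block) or pure noise, and the two
#' classes sit on vertices of a hypercube separated by `class_sep`.
#'
#' @param n_samples number of samples.
#' @param n_features number of features.
#' @param frac_informative fraction of informative features (default 0.30).
#' @param frac_redundant fraction of redundant features (default 0.70);
#'   `frac_informative + frac_redundant` must not exceed 1, any remainder
#'   becomes independent noise features.
#' @param class_sep nonnegative class separation `d`: the hypercube
#'   vertices carrying the two class centroids lie at coordinates
#'   `± class_sep`. `d = 0` places both centroids at the origin, leaving
#'   only the class-specific covariance structure to distinguish classes.
#' @param tn_proportion proportion of true negatives, in (0, 1).
#' @param seed integer master seed for generation.
#' @return an object of class `"synthetic_config"`.
#' @seealso [generate_synthetic()]
#' @export
synthetic_config <- function(n_samples = 200, n_features = 200,
                             frac_informative = 0.30, frac_redundant = 0.70,
                             class_sep = 1, tn_proportion = 0.5,
                             seed = 1) {
  stopifnot(n_samples >= 2, n_features >= 1, class_sep >= 0)
  if (frac_informative < 0 || frac_redundant < 0 ||
      frac_informative + frac_redundant > 1 + 1e-12)
    stop("frac_informative + frac_redundant must lie in [0, 1]")
  if (tn_proportion <= 0 || tn_proportion >= 1)
    stop("tn_proportion must lie strictly between 0 and 1")
  n_informative <- round(frac_informative * n_features)
  if (n_informative < 1)
    stop("configuration yields zero informative features")
  structure(
    list(n_samples = as.integer(n_samples),
         n_features = as.integer(n_features),
         frac_informative = frac_informative,
         frac_redundant = frac_redundant,
         class_sep = class_sep,
         tn_proportion = tn_proportion,
         seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Generate a labeled two-class synthetic dataset
#'
#' Each class is a Gaussian cluster placed at a class-specific vertex of a
#' `[-class_sep, class_sep]` hypercube in the informative-feature subspace.
#' Informative coordinates are drawn standard normal and passed through a
#' class-specific random linear map (entries uniform on \[-1, 1\]), giving
#' each class its own covariance structure, before the centroid is added.
#' Redundant features are exact random linear combinations of the
#' informative block shared across classes; any remaining features are
#' independent standard normal noise. True-positive samples come first,
#' then true negatives; counts follow `tn_proportion` (rounded to nearest,
#' remainder assigned to the positive class).
#'
#' Note that because each class receives its own covariance transform, the
#' two classes remain partially distinguishable even at `class_sep = 0`;
#' only their mean structure coincides.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `"labeled_dataset"`: a list with `features`
#'   (numeric matrix with sample/feature dimnames) and `truth_labels`
#'   (integer vector, 1 = true positive, 0 = true negative).
#' @examples
#' d <- generate_synthetic(synthetic_config(n_samples = 60, n_features = 20,
#'                                          class_sep = 2, seed = 7))
#' table(d$truth_labels)
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_samples
  p <- config$n_features
  n_inf <- round(config$frac_informative * p)
  n_red <- round(config$frac_redundant * p)
  if (n_inf + n_red > p) n_red <- p - n_inf
  n_noise <- p - n_inf - n_red
  n_tn <- round(n * config$tn_proportion)
  n_tp <- n - n_tn
  if (n_tn < 1 || n_tp < 1)
    stop("tn_proportion leaves one class empty at this n_samples")

  set.seed(derive_seed(config$seed, "generate"))

  # two distinct hypercube vertices, scaled to +/- class_sep
  repeat {
    v <- matrix(rbinom(2 * n_inf, 1, 0.5), nrow = 2)
    if (any(v[1, ] != v[2, ])) break
  }
  centroids <- (2 * v - 1) * config$class_sep  # row 1: TP, row 2: TN

  cluster <- function(n_k, centroid) {
    z <- matrix(rnorm(n_k * n_inf), nrow = n_k)
    a <- matrix(runif(n_inf * n_inf, -1, 1), nrow = n_inf)
    sweep(z %*% a, 2, centroid, "+")
  }
  x_inf <- rbind(cluster(n_tp, centroids[1, ]), cluster(n_tn, centroids[2, ]))

  blocks <- list(x_inf)
  if (n_red > 0) {
    b <- matrix(runif(n_inf * n_red, -1, 1), nrow = n_inf)
    blocks <- c(blocks, list(x_inf %*% b))
  }
  if (n_noise > 0)
    blocks <- c(blocks, list(matrix(rnorm(n * n_noise), nrow = n)))
  features <- do.call(cbind, blocks)
  dimnames(features) <- list(sprintf("s%04d", seq_len(n)),
                             sprintf("f_%04d", seq_len(p)))

  structure(list(features = features,
                 truth_labels = c(rep(1L, n_tp), rep(0L, n_tn)),
                 config = config),
            class = "labeled_dataset")
}

#' Construct a positive-unlabeled dataset
#'
#' @param features numeric matrix, samples in rows.
#' @param pu_labels integer vector: 1 = known positive (KP), 0 = unlabeled.
#' @param truth_labels optional integer vector of hidden ground truth
#'   (1 = true positive), used for evaluation only — no modeling function
#'   in this package reads it.
#' @return an object of class `"pu_dataset"`.
#' @export
pu_dataset <- function(features, pu_labels, truth_labels = NULL) {
  features <- as.matrix(features)
  if (anyNA(features)) stop("features contain missing values")
  pu_labels <- as.integer(pu_labels)
  if (length(pu_labels) != nrow(features))
    stop("pu_labels length must equal nrow(features)")
  if (!all(pu_labels %in% c(0L, 1L)))
    stop("pu_labels must be 0/1")
  if (!is.null(truth_labels)) {
    truth_labels <- as.integer(truth_labels)
    if (length(truth_labels) != nrow(features))
      stop("truth_labels length must equal nrow(features)")
    if (any(pu_labels == 1L & truth_labels != 1L))
      stop("every known positive must have truth label 1")
  }
  if (is.null(rownames(features)))
    rownames(features) <- sprintf("s%04d", seq_len(nrow(features)))
  structure(list(features = features, pu_labels = pu_labels,
                 truth_labels = truth_labels),
            class = "pu_dataset")
}

#' Convert a labeled dataset to a positive-unlabeled scenario
#'
#' Draws `n_kp` known positives uniformly without replacement from the
#' true-positive class; every other sample becomes unlabeled. Ground truth
#' is retained on the returned object for evaluation only.
#'
#' @param dataset a `"labeled_dataset"` (see [generate_synthetic()]), or
#'   any list with `features` and `truth_labels`.
#' @param n_kp number of known positives to reveal; must satisfy
#'   `1 <= n_kp <=` number of true positives.
#' @param seed integer seed for the draw.
#' @return a [pu_dataset()].
#' @export
relabel_pu <- function(dataset, n_kp, seed = 1) {
  truth <- as.integer(dataset$truth_labels)
  tp_idx <- which(truth == 1L)
  if (n_kp <= 0) stop("n_kp must be positive")
  if (n_kp > length(tp_idx))
    stop("n_kp (", n_kp, ") exceeds the number of true positives (",
         length(tp_idx), ")")
  set.seed(derive_seed(seed, "relabel"))
  kp <- sample(tp_idx, n_kp)
  pu <- integer(length(truth))
  pu[kp] <- 1L
  pu_dataset(dataset$features, pu, truth)
}

#' @export
print.pu_dataset <- function(x, ...) {
  cat("PU dataset:", nrow(x$features), "samples x", ncol(x$features),
      "features\n")
  cat("  known positives:", sum(x$pu_labels == 1L),
      " unlabeled:", sum(x$pu_labels == 0L), "\n")
  if (!is.null(x$truth_labels))
    cat("  ground truth present (", sum(x$truth_labels == 1L), "TP /",
        sum(x$truth_labels == 0L), "TN ) - evaluation only\n")
  invisible(x)
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled dataset:", nrow(x$features), "samples x", ncol(x$features),
      "features;", sum(x$truth_labels == 1L), "TP /",
      sum(x$truth_labels == 0L), "TN\n")
  invisible(x)
}
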