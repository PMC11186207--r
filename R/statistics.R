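#' Upper-tailed z-score against the permutation null
#'
#' Computes \eqn{z = (\mu - \mu_0)/\sigma}, where \eqn{\mu} is the mean
#' actual-label score over the repeated spy runs, \eqn{\mu_0} the mean of
#' the permutation-null draws, and \eqn{\sigma} the sample standard
#' deviation of the null draws (n - 1 degrees of freedom). The p-value is
#' the upper-tail standard-normal probability, testing the hypothesis
#' that the actual positives score higher than chance
#' (\eqn{\mu > \mu_0}); scores below the null mean yield p > 0.5, never
#' "significance in reverse".
#'
#' @param actual_scores numeric vector of per-repeat scores under the
#'   actual labels.
#' @param null_scores numeric vector of null draws (length >= 2).
#' @return list with `z`, `p_value`, `mu`, `mu0`, `sigma`.
#' @examples
#' z_test(0.9, c(0.4, 0.5, 0.6))
#' @export
z_test <- function(actual_scores, null_scores) {
  if (length(actual_scores) < 1L) stop("actual_scores is empty")
  if (length(null_scores) < 2L)
    stop("z_test requires at least two null draws")
  mu <- mean(actual_scores)
  mu0 <- mean(null_scores)
  sigma <- sd(null_scores)
  if (sigma == 0)
    stop("degenerate null distribution: all permutation draws identical ",
         "(sigma = 0); z-score undefined")
  z <- (mu - mu0) / sigma
  list(z = z, p_value = pnorm(z, lower.tail = FALSE),
       mu = mu, mu0 = mu0, sigma = sigma)
}

#' Cliff's Delta effect size with confidence interval
#'
#' Nonparametric effect size between two samples:
#' \deqn{\delta = \frac{\#\{a_i > b_j\} - \#\{a_i < b_j\}}{|a|\,|b|}}
#' the difference between the probabilities that a draw from `a` exceeds
#' one from `b` and vice versa, in \[-1, 1\]. The confidence interval uses
#' Cliff's consistent variance estimate with the asymmetric
#' transformation, clamped to \[-1, 1\]. Magnitude labels follow the
#' conventional thresholds on \eqn{|\delta|}: negligible < 0.147 <= small
#' < 0.33 <= medium < 0.474 <= large.
#'
#' @param a numeric vector (typically actual-label scores).
#' @param b numeric vector (typically null draws).
#' @param conf_level confidence level (default 0.95).
#' @return list with `estimate`, `ci_low`, `ci_high`, `magnitude`,
#'   `conf_level`. The CI is `NA` when either sample has fewer than two
#'   values.
#' @examples
#' cliffs_delta(c(1, 2), c(1, 3))   # estimate -0.25
#' @export
cliffs_delta <- function(a, b, conf_level = 0.95) {
  if (length(a) < 1L || length(b) < 1L)
    stop("cliffs_delta requires non-empty samples")
  n1 <- length(a)
  n2 <- length(b)
  dom <- sign(outer(a, b, "-"))
  d <- mean(dom)

  if (n1 >= 2L && n2 >= 2L) {
    di <- rowMeans(dom)
    dj <- colMeans(dom)
    s2 <- (n2^2 * sum((di - d)^2) + n1^2 * sum((dj - d)^2) -
             sum((dom - d)^2)) / (n1 * n2 * (n1 - 1) * (n2 - 1))
    s2 <- max(s2, 0)
    zc <- qnorm(1 - (1 - conf_level) / 2)
    den <- 1 - d^2 + zc^2 * s2
    if (den <= 0) {
      ci <- c(d, d)
    } else {
      half <- zc * sqrt(s2) * sqrt((1 - d^2)^2 + zc^2 * s2)
      ci <- (d - d^3 + c(-1, 1) * half) / den
    }
    ci <- pmin(pmax(ci, -1), 1)
  } else {
    ci <- c(NA_real_, NA_real_)
  }

  list(estimate = d, ci_low = ci[1], ci_high = ci[2],
       magnitude = delta_magnitude(d), conf_level = conf_level)
}

#' Magnitude label for a Cliff's Delta estimate
#'
#' @param delta Cliff's Delta estimate in \[-1, 1\].
#' @return one of `"negligible"`, `"small"`, `"medium"`, `"large"`.
#' @export
delta_magnitude <- function(delta) {
  ad <- abs(delta)
  if (ad < 0.147) "negligible"
  else if (ad < 0.33) "small"
  else if (ad < 0.474) "medium"
  else "large"
}

#' ROC-AUC of the unlabeled set against hidden ground truth
#'
#' Rank-based ROC-AUC between the PU bagging scores of the unlabeled
#' samples and their held-out ground-truth labels (hidden true positives
#' as class 1). Equivalent to the normalized Mann-Whitney U statistic;
#' tied scores contribute one half. This is an evaluation-only oracle
#' metric: it requires ground truth that real PU applications lack.
#'
#' @param scores numeric vector of bagging scores over the U set, or a
#'   `"pu_bagging_result"` (its `scores` are used).
#' @param truth_labels 0/1 ground truth for the same samples; both
#'   classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' u_auc(c(0.9, 0.4, 0.4, 0.1), c(1, 1, 0, 0))  # 0.875
#' @export
u_auc <- function(scores, truth_labels) {
  if (inherits(scores, "pu_bagging_result")) scores <- scores$scores
  truth_labels <- as.integer(truth_labels)
  if (length(scores) != length(truth_labels))
    stop("scores and truth_labels must have equal length")
  n1 <- sum(truth_labels == 1L)
  n0 <- sum(truth_labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("u_auc requires both classes among the unlabeled samples")
  r <- rank(scores)
  (sum(r[truth_labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
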