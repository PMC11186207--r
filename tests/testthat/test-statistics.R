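# brute-force oracles, kept deliberately independent of the implementation

oracle_cliffs <- function(a, b) {
  gt <- 0; lt <- 0
  for (x in a) for (y in b) {
    if (x > y) gt <- gt + 1
    if (x < y) lt <- lt + 1
  }
  (gt - lt) / (length(a) * length(b))
}

oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

test_that("z_test matches the printed formula exactly", {
  # null c(0.4, 0.5, 0.6): mean 0.5, sd 0.1
  res <- z_test(0.9, c(0.4, 0.5, 0.6))
  expect_equal(res$z, 4.0)
  expect_equal(res$p_value, pnorm(4, lower.tail = FALSE))
  expect_equal(res$p_value, 3.167124e-05, tolerance = 1e-6)

  same <- z_test(c(0.5, 0.5), c(0.4, 0.5, 0.6))
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 0.5)

  worse <- z_test(0.3, c(0.4, 0.5, 0.6))
  expect_gt(worse$p_value, 0.5)

  set.seed(4)
  for (i in 1:10) {
    act <- runif(7); nul <- runif(12)
    r <- z_test(act, nul)
    expect_equal(r$z, (mean(act) - mean(nul)) / sd(nul))
    expect_equal(r$sigma, sd(nul))  # n - 1 degrees of freedom
  }
})

test_that("z_test rejects degenerate or underpowered nulls", {
  expect_error(z_test(0.9, rep(0.5, 10)), "degenerate")
  expect_error(z_test(0.9, 0.5), "at least two")
  expect_error(z_test(numeric(0), c(0.4, 0.6)), "empty")
})

test_that("cliffs_delta agrees with brute-force pair counting", {
  expect_equal(cliffs_delta(c(1, 2), c(1, 3))$estimate, -0.25)
  expect_equal(cliffs_delta(5:8, 1:4)$estimate, 1.0)
  expect_equal(cliffs_delta(c(1, 2, 3), c(3, 1, 2))$estimate, 0.0)

  set.seed(7)
  for (i in 1:20) {
    a <- sample(seq(0, 1, by = 0.1), sample(2:12, 1), replace = TRUE)
    b <- sample(seq(0, 1, by = 0.1), sample(2:12, 1), replace = TRUE)
    est <- cliffs_delta(a, b)$estimate
    expect_equal(est, oracle_cliffs(a, b))
    expect_gte(est, -1); expect_lte(est, 1)
    # antisymmetry
    expect_equal(cliffs_delta(b, a)$estimate, -est)
    # invariance under a strictly monotone transform
    expect_equal(cliffs_delta(exp(a), exp(b))$estimate, est)
  }
})

test_that("cliffs_delta confidence interval brackets the estimate in [-1, 1]", {
  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(sample(3:15, 1)); b <- rnorm(sample(3:15, 1))
    r <- cliffs_delta(a, b)
    expect_lte(r$ci_low, r$estimate)
    expect_gte(r$ci_high, r$estimate)
    expect_gte(r$ci_low, -1); expect_lte(r$ci_high, 1)
  }
  # clear separation: the interval stays on the positive side
  sep <- cliffs_delta(rnorm(30, 5), rnorm(30, 0))
  expect_gt(sep$ci_low, 0)
  expect_equal(sep$magnitude, "large")
  expect_error(cliffs_delta(numeric(0), 1:3), "non-empty")
})

test_that("magnitude labels follow the 0.147/0.33/0.474 boundaries", {
  expect_equal(delta_magnitude(0.10), "negligible")
  expect_equal(delta_magnitude(-0.10), "negligible")
  expect_equal(delta_magnitude(0.2), "small")
  expect_equal(delta_magnitude(0.4), "medium")
  expect_equal(delta_magnitude(0.50), "large")
  expect_equal(delta_magnitude(-0.95), "large")
})

test_that("u_auc equals exhaustive pair counting and handles ties", {
  expect_equal(u_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(u_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0.0)
  expect_equal(u_auc(c(0.9, 0.4, 0.4, 0.1), c(1, 1, 0, 0)), 0.875)

  set.seed(9)
  for (i in 1:15) {
    n <- sample(6:50, 1)
    truth <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)
    expect_equal(u_auc(scores, truth), oracle_auc(scores, truth))
  }
  expect_error(u_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("u_auc matches the normalized Mann-Whitney U statistic", {
  set.seed(10)
  for (i in 1:10) {
    n1 <- sample(3:25, 1); n0 <- sample(3:25, 1)
    pos <- sample(seq(0, 1, 0.1), n1, replace = TRUE)
    neg <- sample(seq(0, 1, 0.1), n0, replace = TRUE)
    w <- suppressWarnings(
      stats::wilcox.test(pos, neg, exact = FALSE)$statistic)
    expect_equal(u_auc(c(pos, neg), rep(c(1, 0), c(n1, n0))),
                 unname(w) / (n1 * n0))
  }
})

test_that("u_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  scores <- runif(40)
  truth <- rbinom(40, 1, 0.5)
  truth[1:2] <- c(0, 1)
  expect_equal(u_auc(scores, truth),
               as.numeric(suppressMessages(pROC::auc(truth, scores))))
})
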