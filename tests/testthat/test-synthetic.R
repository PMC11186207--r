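test_that("class counts follow tn_proportion, with TP first", {
  d <- generate_synthetic(synthetic_config(200, 200, tn_proportion = 0.5,
                                           seed = 3))
  expect_equal(sum(d$truth_labels == 0L), 100)
  expect_equal(sum(d$truth_labels == 1L), 100)

  d2 <- generate_synthetic(synthetic_config(100, 20, tn_proportion = 0.3,
                                            seed = 3))
  expect_equal(sum(d2$truth_labels == 0L), 30)
  expect_equal(length(d2$truth_labels), 100)
  expect_false(anyNA(d2$features))
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- synthetic_config(60, 30, class_sep = 1, tn_proportion = 0.4,
                          seed = 11)
  a <- generate_synthetic(cfg)
  b <- generate_synthetic(cfg)
  expect_identical(a$features, b$features)
  expect_identical(a$truth_labels, b$truth_labels)
  cfg2 <- synthetic_config(60, 30, class_sep = 1, tn_proportion = 0.4,
                           seed = 12)
  expect_false(identical(generate_synthetic(cfg2)$features, a$features))
})

test_that("redundant features keep the matrix rank at the informative count", {
  d <- generate_synthetic(synthetic_config(100, 200,
                                           frac_informative = 0.30,
                                           frac_redundant = 0.70,
                                           class_sep = 1, seed = 5))
  # 60 informative columns span everything: 140 redundant columns are
  # exact linear combinations, so numerical rank <= 60
  expect_lte(qr(d$features)$rank, 60)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(frac_informative = 0.6, frac_redundant = 0.6),
               "frac_informative")
  expect_error(synthetic_config(tn_proportion = 0), "tn_proportion")
  expect_error(synthetic_config(tn_proportion = 1), "tn_proportion")
  expect_error(synthetic_config(n_features = 10, frac_informative = 0.01,
                                frac_redundant = 0.5), "informative")
})

test_that("relabel_pu draws KP only from true positives and conserves counts", {
  # Lakhashe-shaped input: 108 instances, 72 TP (1/3 TN), 10 KP
  cfg <- synthetic_config(108, 20, tn_proportion = 1 / 3, seed = 9)
  d <- generate_synthetic(cfg)
  expect_equal(sum(d$truth_labels == 0L), 36)
  pu <- relabel_pu(d, n_kp = 10, seed = 2)
  expect_equal(sum(pu$pu_labels == 1L), 10)
  expect_equal(sum(pu$pu_labels == 0L), 98)
  expect_true(all(pu$truth_labels[pu$pu_labels == 1L] == 1L))

  # exhaustive selection: U reduces to exactly the TN set
  pu_all <- relabel_pu(d, n_kp = 72, seed = 2)
  expect_setequal(which(pu_all$pu_labels == 0L),
                  which(d$truth_labels == 0L))

  expect_error(relabel_pu(d, n_kp = 73), "exceeds")
  expect_error(relabel_pu(d, n_kp = 0), "positive")
})

test_that("relabel_pu is reproducible and seed-sensitive", {
  d <- generate_synthetic(synthetic_config(50, 10, seed = 1))
  expect_identical(relabel_pu(d, 8, seed = 4)$pu_labels,
                   relabel_pu(d, 8, seed = 4)$pu_labels)
  expect_false(identical(relabel_pu(d, 8, seed = 4)$pu_labels,
                         relabel_pu(d, 8, seed = 5)$pu_labels))
})

test_that("classification difficulty decreases with class separation", {
  # mean held-out AUC of a fixed SVM over seeds must be non-decreasing
  # in d across 0, 1, 2
  mean_auc <- function(d) {
    mean(sapply(1:20, function(s) {
      dat <- generate_synthetic(synthetic_config(60, 30, class_sep = d,
                                                 tn_proportion = 0.5,
                                                 seed = 100 * s + d))
      train <- c(1:15, 31:45)  # half of each class (TP rows first)
      fit <- e1071::svm(dat$features[train, ],
                        factor(dat$truth_labels[train]), kernel = "radial")
      pr <- predict(fit, dat$features[-train, ], decision.values = TRUE)
      dvm <- attr(pr, "decision.values")
      # orient decision values toward class "1"
      sgn <- if (startsWith(colnames(dvm)[1], "1")) 1 else -1
      u_auc(sgn * dvm[, 1], dat$truth_labels[-train])
    }))
  }
  aucs <- sapply(c(0, 1, 2), mean_auc)
  expect_true(all(diff(aucs) >= 0))
  expect_gt(aucs[3], 0.9)
})

test_that("pu_dataset validates its invariants", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(pu_dataset(x, rep(1L, 9)), "length")
  expect_error(pu_dataset(x, rep(2L, 10)), "0/1")
  expect_error(pu_dataset(x, c(1L, rep(0L, 9)), c(0L, rep(1L, 9))),
               "known positive")
  x[1, 1] <- NA
  expect_error(pu_dataset(x, rep(0L, 10)), "missing")
})
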