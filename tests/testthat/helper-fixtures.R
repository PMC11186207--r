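# Mock classifiers honouring the fit_predict contract, and small fixtures.
# Mocks keep combinatorial/property tests fast; real-SVM behavior is
# exercised separately on toy geometries and in the acceptance tests.

mock_classifier_feature1 <- function(threshold = 0) {
  function(train_x, train_y, test_x) {
    if (length(unique(train_y)) < 2L) stop("single-class training set")
    as.integer(test_x[, 1] > threshold)
  }
}

mock_classifier_constant <- function(value) {
  force(value)
  function(train_x, train_y, test_x) {
    if (length(unique(train_y)) < 2L) stop("single-class training set")
    rep(as.integer(value), nrow(test_x))
  }
}

# Small synthetic PU dataset
tiny_pu <- function(n = 40, p = 10, d = 2, tn = 0.5, n_kp = 8, seed = 1) {
  cfg <- synthetic_config(n_samples = n, n_features = p, class_sep = d,
                          tn_proportion = tn, seed = seed)
  relabel_pu(generate_synthetic(cfg), n_kp = n_kp, seed = seed)
}

# 2-D toy geometry: KP and hidden TP cluster at (+5,+5), hidden TN at
# (-5,-5); trivially separable, so a sane PU bagging run must rank every
# hidden TP above every hidden TN.
toy_clouds_pu <- function(n_kp = 8, n_hidden_tp = 6, n_tn = 6, seed = 42,
                          spread = 0.5) {
  set.seed(seed)
  pos <- matrix(rnorm((n_kp + n_hidden_tp) * 2, mean = 5, sd = spread),
                ncol = 2)
  neg <- matrix(rnorm(n_tn * 2, mean = -5, sd = spread), ncol = 2)
  features <- rbind(pos, neg)
  truth <- c(rep(1L, n_kp + n_hidden_tp), rep(0L, n_tn))
  pu <- c(rep(1L, n_kp), rep(0L, n_hidden_tp + n_tn))
  pu_dataset(features, pu, truth)
}
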