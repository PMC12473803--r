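# cross-checks of the in-package model fits against independent references

test_that("ridge logistic matches glmnet at the equivalent penalty", {
  skip_if_not_installed("glmnet")
  set.seed(30)
  n <- 80; p <- 6
  X <- matrix(rnorm(n * p), n)
  y <- factor(ifelse(X[, 1] + 0.5 * X[, 2] + rnorm(n) > 0, "PD", "Control"),
              levels = c("Control", "PD"))
  fit <- tugcop:::fit_lr(X, y, C = 1)
  w <- tugcop:::balanced_obs_weights(y)
  g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                      lambda = 1 / n, weights = w, standardize = FALSE,
                      thresh = 1e-12)
  p_mine <- tugcop:::predict_lr(fit, X)
  p_ref <- as.numeric(predict(g, X, type = "response"))
  expect_lt(max(abs(p_mine - p_ref)), 5e-3)
  expect_gt(cor(p_mine, p_ref), 0.9999)
})

test_that("Gaussian NB matches a direct log-density oracle and e1071 labels", {
  set.seed(31)
  n <- 60
  X <- cbind(rnorm(n, ifelse(1:n <= 30, 0, 1.5)), rnorm(n, sd = 2))
  y <- factor(rep(c("Control", "PD"), each = 30), levels = c("Control", "PD"))
  fit <- tugcop:::fit_nb(X, y)
  pred <- tugcop:::predict_nb(fit, X)

  # naive oracle with population variances and frequency priors
  oracle_lp <- sapply(c("Control", "PD"), function(g) {
    Xi <- X[y == g, ]
    mu <- colMeans(Xi)
    v <- colMeans(sweep(Xi, 2, mu)^2)
    sapply(seq_len(n), function(i) {
      sum(dnorm(X[i, ], mu, sqrt(v), log = TRUE)) + log(nrow(Xi) / n)
    })
  })
  oracle_lab <- c("Control", "PD")[max.col(oracle_lp)]
  expect_equal(as.character(pred$labels), oracle_lab)
  oracle_post <- exp(oracle_lp[, 2]) / rowSums(exp(oracle_lp))
  expect_equal(pred$score, oracle_post, tolerance = 1e-6)

  ref <- predict(e1071::naiveBayes(X, y), X)
  expect_gt(mean(as.character(ref) == as.character(pred$labels)), 0.95)
})

test_that("the deterministic 5-NN vote matches class::knn", {
  set.seed(32)
  Xtr <- matrix(rnorm(200), 50)
  ytr <- factor(sample(c("Control", "PD"), 50, TRUE),
                levels = c("Control", "PD"))
  Xte <- matrix(rnorm(80), 20)
  mine <- tugcop:::knn_vote(tugcop:::sq_dist(Xte, Xtr), ytr, k = 5L)
  ref <- class::knn(Xtr, Xte, ytr, k = 5)
  expect_equal(as.character(mine$labels), as.character(ref))
  expect_true(all(mine$score %in% c(0, 0.2, 0.4, 0.6, 0.8, 1)))
})

test_that("every family fits, predicts and scores on a toy problem", {
  set.seed(33)
  tab <- toy_feature_table(n_per_class = 15L, effect = 2.5, seed = 33)
  sp <- make_split(tab, 0.2, 33L)
  feats <- scenario_feature_names()[1:3]
  for (m in c("svm", "lr", "rf", "knn", "nb")) {
    rep <- evaluate_model(sp$train, sp$test, m, feats)
    expect_s3_class(rep, "evaluation_report")
    expect_equal(sum(rep$confusion), nrow(sp$test))
    expect_true(all(rep$scores >= 0 & rep$scores <= 1))
    expect_gte(rep$metrics$accuracy, 0.5)  # strongly separable toy signal
  }
})

test_that("an all-constant design falls back to a majority-class predictor", {
  # degenerate features occur in practice (e.g. a quantized spectral mode equal
  # on both feet gives an identically-zero asymmetry column)
  y <- factor(rep(c("Control", "PD"), c(14, 12)), levels = c("Control", "PD"))
  Xc <- matrix(1.5, 26, 2)
  for (m in c("svm", "lr", "rf", "knn", "nb")) {
    pred <- tugcop:::fit_predict_labels(m, Xc, y, matrix(1.5, 4, 2))
    expect_equal(as.character(pred), rep("Control", 4))
  }
  fit <- tugcop:::fit_final_model("rf", Xc, y)
  out <- tugcop:::predict_final_model(fit, matrix(1.5, 3, 2))
  expect_equal(as.character(out$labels), rep("Control", 3))
  expect_equal(out$score, rep(0.5, 3))
})
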