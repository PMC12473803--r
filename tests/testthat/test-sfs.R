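test_that("a single separating feature is picked first with best_k = 1", {
  tab <- toy_feature_table(n_per_class = 15L, informative = 5L, effect = 4,
                           seed = 40)
  sp <- make_split(tab, 0.2, 40L)
  sel <- select_features(sp$train, "lr", k_grid = 1:3)
  expect_equal(sel$path$feature[1], scenario_feature_names()[5])
  expect_equal(sel$best_k, 1L)
  expect_length(sel$features, 1L)
})

test_that("the first greedy pick maximizes single-feature inner-CV F1 (NB oracle)", {
  tab <- toy_feature_table(n_per_class = 12L, informative = 3L, effect = 2,
                           seed = 41)
  nm <- scenario_feature_names()[1:10]
  small <- tab[, c("participant_id", "group", "scenario", nm)]
  sel <- select_features(small, "nb", k_grid = 1:2)

  # independent brute force: same stratified folds, e1071 naive Bayes
  y <- factor(small$group, levels = c("Control", "PD"))
  fold <- tugcop:::stratified_folds(y, 5L, 42L)
  oracle <- sapply(nm, function(f) {
    mean(sapply(1:5, function(k) {
      tr <- fold != k
      fit <- e1071::naiveBayes(data.frame(x = small[[f]][tr]), y[tr])
      pred <- predict(fit, data.frame(x = small[[f]][!tr]))
      tugcop:::f1_score(y[!tr], pred)
    }))
  })
  expect_equal(sel$path$feature[1], nm[which.max(oracle)])
  expect_equal(unname(sel$path$mean_f1[1]), unname(max(oracle)), tolerance = 1e-9)
})

test_that("a duplicated informative feature is selected only once before noise", {
  tab <- toy_feature_table(n_per_class = 15L, informative = 1L, effect = 4,
                           seed = 42, duplicate = TRUE)
  nm <- scenario_feature_names()[1:5]
  small <- tab[, c("participant_id", "group", "scenario", nm)]
  sel <- select_features(small, "nb", k_grid = 1:4)
  first_two <- sel$path$feature[1:2]
  expect_true(nm[1] %in% first_two[1])       # informative copy first
  expect_false(nm[2] %in% first_two)         # duplicate adds no gain
})

test_that("selection depends only on the training partition (no leakage)", {
  tab <- toy_feature_table(n_per_class = 12L, informative = 2L, effect = 2,
                           seed = 43)
  sp <- make_split(tab, 0.2, 43L)
  sel1 <- select_features(sp$train, "nb", k_grid = 1:3)

  corrupted <- sp$test
  feat_cols <- scenario_feature_names()
  corrupted[, feat_cols] <- corrupted[, feat_cols] + 100
  sel2 <- select_features(sp$train, "nb", k_grid = 1:3)
  expect_identical(sel1$path, sel2$path)
  # ... while the held-out evaluation does change
  r1 <- evaluate_model(sp$train, sp$test, "nb", sel1$features)
  r2 <- evaluate_model(sp$train, corrupted, "nb", sel1$features)
  expect_false(identical(r1$scores, r2$scores))
})

test_that("grid bounds and degenerate inputs are rejected", {
  tab <- toy_feature_table(n_per_class = 8L, seed = 44)
  sp <- make_split(tab, 0.25, 44L)
  expect_error(select_features(sp$train, "nb", k_grid = 1:200), "exceeds")
  expect_error(select_features(sp$train, "nb", k_grid = integer()), "non-empty")
  one_class <- sp$train
  one_class$group <- "PD"
  expect_error(select_features(one_class, "nb", k_grid = 1:2))
})
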