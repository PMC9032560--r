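# Two-level medical feature regression structure.

test_that("sigmoid probabilization of the decision score is exact and monotone", {
  expect_equal(1 / (1 + exp(-0)), 0.5)
  toy <- toy_medical_data()
  m <- train_stage1(toy$features, toy$obstructed)
  z <- decision_score(m, toy$features)
  p <- obstruction_probability(m, toy$features)
  expect_equal(p, 1 / (1 + exp(-z)))
  expect_true(all(p > 0 & p < 1))
  # strictly monotone transform: ordering preserved
  expect_equal(order(z), order(p))
})

test_that("stage 1 separates a separable toy set and beats the base rate", {
  toy <- toy_medical_data()
  m <- train_stage1(toy$features, toy$obstructed)
  pred <- obstruction_probability(m, toy$features) > 0.5
  expect_equal(mean(pred == toy$obstructed), 1.0)
})

test_that("stage 1 rejects degenerate label sets", {
  toy <- toy_medical_data()
  expect_error(train_stage1(toy$features, rep(TRUE, nrow(toy$features))),
               class = "capnopred_degenerate_labels")
  expect_error(train_stage1(toy$features[0, ], logical(0)),
               class = "capnopred_invalid_argument")
})

test_that("feature fusion appends the probability as the last coordinate", {
  toy <- toy_medical_data(n = 10)
  p <- runif(10, 0.1, 0.9)
  fused <- fuse_features(toy$features, p)
  expect_equal(ncol(fused), 16)
  expect_equal(unname(fused[, 16]), p)
  expect_equal(colnames(fused)[16], "obstruction_prob")
  # fuse-then-drop is the identity on the original features
  expect_equal(fused[, 1:15],
               capnopred:::medical_feature_matrix(toy$features))
  # two rows differing only in p differ only in the last coordinate
  f2 <- fuse_features(toy$features, rev(p))
  expect_equal(fused[, 1:15], f2[, 1:15])
})

test_that("missing feature values are rejected by validation", {
  toy <- toy_medical_data(n = 12)
  toy$features$age[3] <- NA
  expect_error(train_stage1(toy$features, toy$obstructed),
               class = "capnopred_invalid_argument")
})

test_that("stage 2 reproduces constant targets and is seeded-deterministic", {
  toy <- toy_medical_data(n = 40)
  fused <- fuse_features(toy$features, rep(0.5, 40))
  const <- cbind(rep(2.5, 40), rep(3.5, 40))
  m <- train_stage2(fused, const, seed = 4)
  dm <- xgboost::xgb.DMatrix(fused)
  expect_equal(unname(predict(m$boosters$fev1, dm)), rep(2.5, 40),
               tolerance = 1e-3)
  expect_equal(unname(predict(m$boosters$fvc, dm)), rep(3.5, 40),
               tolerance = 1e-3)
  m2 <- train_stage2(fused, const, seed = 4)
  expect_equal(predict(m$boosters$fvc, dm), predict(m2$boosters$fvc, dm))
  expect_error(train_stage2(fused[1:5, ], const[1:5, ]),
               class = "capnopred_invalid_argument")
})

test_that("stage-2 in-sample fit beats the constant-mean predictor", {
  toy <- toy_medical_data(n = 50, seed = 8)
  m <- train_medical(toy$features, toy$targets, seed = 2)
  p <- predict_medical(m, toy$features)
  for (j in 1:2) {
    rmse_model <- sqrt(mean((p[, j] - toy$targets[, j])^2))
    rmse_const <- sqrt(mean((toy$targets[, j] - mean(toy$targets[, j]))^2))
    expect_lt(rmse_model, rmse_const)
  }
})

test_that("feature importance covers all fused features and normalizes", {
  toy <- toy_medical_data(n = 40, seed = 3)
  m <- train_medical(toy$features, toy$targets, seed = 2)
  imp <- stage2_importance(m$stage2)
  expect_equal(nrow(imp), 16)
  expect_setequal(imp$feature, c(medical_feature_names, "obstruction_prob"))
  expect_equal(sum(imp$gain_fev1), 1, tolerance = 1e-9)
  expect_equal(sum(imp$gain_fvc), 1, tolerance = 1e-9)
})

test_that("hyperparameter search is deterministic and honors single grids", {
  toy <- toy_medical_data(n = 40, seed = 5)
  fused <- fuse_features(toy$features, rep(0.5, 40))
  single <- list(list(nrounds = 30, max_depth = 2))
  sel <- heuristic_search(single, fused, toy$targets, seed = 9)
  expect_equal(sel$nrounds, 30)
  grid <- list(list(nrounds = 20, max_depth = 2, eta = 0.2),
               list(nrounds = 40, max_depth = 3, eta = 0.1))
  s1 <- heuristic_search(grid, fused, toy$targets, seed = 9)
  s2 <- heuristic_search(grid, fused, toy$targets, seed = 9)
  expect_identical(s1, s2)
  expect_error(heuristic_search(list(), fused, toy$targets),
               class = "capnopred_invalid_argument")
})

test_that("the full medical pipeline generalizes on a synthetic cohort", {
  co <- cached_cohort(500)
  f <- cohort_features(co)
  tr <- 1:400
  te <- 401:500
  y <- as.matrix(f[c("fev1_l", "fvc_l")])
  m <- train_medical(f[tr, medical_feature_names], y[tr, ], seed = 7)
  # stage-1 held-out accuracy beats chance
  acc <- mean((obstruction_probability(m$stage1,
                                       f[te, medical_feature_names]) > 0.5) ==
                f$obstructed[te])
  expect_gt(acc, 0.5)
  p <- predict_medical(m, f[te, medical_feature_names])
  expect_gt(rmse_r2(p[, 2], y[te, 2])$r2, 0.5)
  expect_true(all(p >= 0.1))
})

test_that("interpolation: an overfit configuration memorizes training points", {
  co <- cached_cohort(500)
  f <- cohort_features(co)[1:80, ]
  y <- as.matrix(f[c("fev1_l", "fvc_l")])
  m <- train_medical(f[medical_feature_names], y,
                     stage2_params = list(nrounds = 600, max_depth = 8,
                                          eta = 0.3, colsample_bytree = 1),
                     seed = 3)
  p <- predict_medical(m, f[medical_feature_names])
  expect_lt(max(abs(p[, 2] - y[, 2])), 0.05)
})

test_that("predict_medical refuses unfitted models", {
  expect_error(predict_medical(structure(list(), class = "list"),
                               toy_medical_data(5)$features),
               class = "capnopred_invalid_state")
})
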