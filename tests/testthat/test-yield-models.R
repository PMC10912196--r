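test_that("model specifications carry the documented defaults", {
  rf <- rf_spec()
  expect_equal(rf$max_depth, 10)
  expect_equal(rf$n_trees, 400)
  xgb <- xgb_spec()
  expect_equal(xgb$learning_rate, 0.06)
  expect_equal(xgb$max_depth, 3)
  expect_equal(xgb$min_child_weight, 5)
  expect_error(model_spec("random_forest", n_trees = 0), "n_trees")
})

test_that("learner wrappers are deterministic and check feature manifests", {
  fx <- signal_fixture(n = 60, n_decoys = 2)
  for (spec in list(rf_spec(n_trees = 100), xgb_spec(n_trees = 50))) {
    f1 <- fit_learner(spec, fx$x, fx$y, seed = 5)
    f2 <- fit_learner(spec, fx$x, fx$y, seed = 5)
    expect_identical(predict_learner(f1, fx$x), predict_learner(f2, fx$x))
    expect_error(predict_learner(f1, fx$x[, 1:3]), "manifest")
    imp <- importance_learner(f1)
    expect_length(imp, ncol(fx$x))
    expect_gt(imp[["x1"]], max(imp[c("d1", "d2")]))
  }
})

test_that("adjusted R2 penalizes model size", {
  r2 <- runif(20, 0, 0.99)
  for (r in r2) {
    expect_lt(adjusted_r2(r, n = 50, p = 5), r + 1e-15)
  }
  expect_equal(adjusted_r2(1, 50, 5), 1)
  expect_error(adjusted_r2(0.5, n = 5, p = 5))
})

test_that("a singleton grid returns itself; the search reproduces brute force", {
  fx <- signal_fixture(n = 80, n_decoys = 2)
  one <- grid_search(rf_spec(), fx$x, fx$y,
                     grid = data.frame(max_depth = 7, n_trees = 120),
                     folds = 4, seed = 11)
  expect_equal(one$best$max_depth, 7)
  expect_equal(one$best$n_trees, 120)

  grid <- expand.grid(max_depth = c(2, 6), n_trees = c(50, 150))
  gs1 <- grid_search(rf_spec(), fx$x, fx$y, grid = grid, folds = 4, seed = 12)
  gs2 <- grid_search(rf_spec(), fx$x, fx$y, grid = grid, folds = 4, seed = 12)
  expect_identical(gs1$best, gs2$best)
  # exhaustive re-scoring oracle: every grid point rescored independently
  rescored <- apply(gs1$scores[c("max_depth", "n_trees")], 1, function(gp) {
    sp <- rf_spec(max_depth = gp[["max_depth"]], n_trees = gp[["n_trees"]])
    kfold(sp, fx$x, fx$y, k = 4, seed = 12)$mean_test_adj_r2
  })
  expect_equal(unname(rescored), gs1$scores$mean_test_adj_r2)
  expect_equal(max(rescored),
               gs1$scores$mean_test_adj_r2[
                 gs1$scores$max_depth == gs1$best$max_depth &
                   gs1$scores$n_trees == gs1$best$n_trees])
})

test_that("MCCV learns a deterministic signal and not pure noise", {
  fx <- signal_fixture(n = 100, n_decoys = 0, noise_sd = 0)
  cv <- mccv(rf_spec(n_trees = 200), fx$x, fx$y, iterations = 30, seed = 13)
  expect_gt(cv$summary$mean_test_adj_r2, 0.85)

  noise <- latentyield:::with_seed(14, rnorm(100))
  cvn <- mccv(rf_spec(n_trees = 150), fx$x, noise, iterations = 50, seed = 15)
  expect_lt(cvn$summary$mean_test_adj_r2, 0.05)
})

test_that("MCCV is reproducible and records the best random state", {
  fx <- signal_fixture(n = 80, n_decoys = 3)
  a <- mccv(xgb_spec(n_trees = 40), fx$x, fx$y, iterations = 25, seed = 16)
  b <- mccv(xgb_spec(n_trees = 40), fx$x, fx$y, iterations = 25, seed = 16)
  expect_identical(a$scores, b$scores)
  expect_identical(a$best_iteration, b$best_iteration)
  expect_identical(predict_all(a, fx$x), predict_all(b, fx$x))
  best <- a$scores[a$scores$iteration == a$best_iteration, ]
  expect_equal(best$test_adj_r2, max(a$scores$test_adj_r2))
  expect_equal(best$n_train + best$n_test, 80)
})

test_that("variable-split MCCV draws several split sizes and skips tiny test sets", {
  fx <- signal_fixture(n = 60, n_decoys = 10)
  cv <- mccv(rf_spec(n_trees = 60), fx$x, fx$y, iterations = 40,
             train_frac = "variable", seed = 17)
  # 13 features: a 0.9 train fraction leaves n_test = 6 <= p + 1, skipped
  expect_gt(length(cv$skipped), 0)
  expect_gt(length(unique(cv$scores$n_train)), 1)
  expect_true(all(cv$scores$n_test > ncol(fx$x) + 1))
})

test_that("k-fold is seeded, guarded, and consistent with MCCV", {
  fx <- signal_fixture(n = 100, n_decoys = 0, noise_sd = 0)
  k1 <- kfold(rf_spec(n_trees = 150), fx$x, fx$y, k = 10, seed = 18)
  k2 <- kfold(rf_spec(n_trees = 150), fx$x, fx$y, k = 10, seed = 18)
  expect_identical(k1, k2)
  expect_error(kfold(rf_spec(), fx$x, fx$y, k = 101), "folds")
  expect_error(kfold(rf_spec(), fx$x, fx$y, k = 100), "too small")
  # protocol agreement on a deterministic fixture at matched train fraction:
  # repeated k-fold (to average out the single-partition draw) vs MCCV
  kf_mean <- mean(sapply(18:27, function(s)
    kfold(rf_spec(n_trees = 150), fx$x, fx$y, k = 10, seed = s)$mean_test_adj_r2))
  cv <- mccv(rf_spec(n_trees = 150), fx$x, fx$y, iterations = 100,
             train_frac = 0.9, seed = 19)
  expect_lt(abs(kf_mean - cv$summary$mean_test_adj_r2), 0.02)
})

test_that("predictions cover every plot and a forest averages its trees", {
  fx <- signal_fixture(n = 50, n_decoys = 1)
  cv <- mccv(rf_spec(n_trees = 80), fx$x, fx$y, iterations = 10, seed = 20)
  preds <- predict_all(cv, fx$x, plot_ids = sprintf("p%02d", 1:50))
  expect_equal(nrow(preds), 50)
  expect_setequal(unique(preds$set_label), c("train", "test"))
  expect_equal(sum(preds$set_label == "train"), length(cv$best_split))

  # two-tree toy forest: the ensemble prediction is the per-tree mean
  toy <- fit_learner(rf_spec(n_trees = 2, max_depth = 0), fx$x, fx$y,
                     seed = 21)
  per_tree <- predict(toy$model, data = fx$x, predict.all = TRUE,
                      num.threads = 1)$predictions
  expect_equal(rowMeans(per_tree), predict_learner(toy, fx$x),
               tolerance = 1e-12)

  # deep unregularized forest nearly interpolates its training data
  deep <- fit_learner(rf_spec(n_trees = 400, max_depth = 0), fx$x, fx$y,
                      seed = 22)
  expect_gt(prediction_r2(fx$y, predict_learner(deep, fx$x)), 0.9)
})
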