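test_that("training is deterministic and refuses unsplit data", {
  ds <- tiny_dataset()
  m1 <- train_descriptor_model(ds, "radius", tiny_config())
  m2 <- train_descriptor_model(ds, "radius", tiny_config())
  expect_identical(m1$metrics$value, m2$metrics$value)

  unsplit <- assemble_dataset(sample_ensemble(3, seed = 1))
  expect_error(train_descriptor_model(unsplit, "radius", tiny_config()),
               "no split tags")
  expect_error(train_descriptor_model(ds, "minor_groove", tiny_config()),
               "must be one of")
})

test_that("a modest noise-free dataset already recovers the radius well", {
  m <- tiny_radius_model()
  expect_gt(m$test_score, 0.85)   # held-out R^2
  expect_equal(m$metrics$split, c("train", "validation", "test"))
})

test_that("grouped cross-validation partitions conformations and nails constant labels", {
  ds <- tiny_dataset()
  cv <- cross_validate(ds, "radius", k = 5, tiny_config())
  expect_length(cv$fold_metrics, 5)
  expect_equal(cv$mean, mean(cv$fold_metrics))
  tab <- table(cv$folds$conformation_id)
  expect_true(all(tab == 1))     # each conformation in exactly one fold
  expect_error(cross_validate(ds, "radius", k = 10000, tiny_config()),
               "exceeds")

  const <- fake_dataset(30)
  const$labels$radius <- 5
  cv0 <- cross_validate(const, "radius", k = 4,
                        training_config(n_trees_cv = 10, seed = 1))
  expect_equal(cv0$mean, 0, tolerance = 1e-6)
  expect_equal(cv0$sd, 0, tolerance = 1e-6)
})

test_that("linear baselines solve a linear toy exactly and reject the classifier", {
  lin <- fake_dataset(60, n_cond = 3, n_q = 6,
                      label_fun = function(i) numeric(4), seed = 5)
  # labels a fixed linear functional of the features
  w <- c(0.5, -1, 2, 0, 1, 0.3)
  y <- as.numeric(lin$features %*% w)
  for (col in c("radius", "twist", "rise", "major_groove_width")) {
    lin$labels[[col]] <- y
  }
  lin <- split_by_conformation(lin, seed = 1)
  tb <- linear_baselines(lin, "radius", ridge_lambdas = c(0, 1e-6))
  expect_equal(tb$model, c("linear", "ridge", "lasso"))
  expect_lt(tb$test_mse[tb$model == "linear"], 1e-10)
  # ridge at (effectively) zero penalty equals unregularized regression
  expect_equal(tb$test_mse[tb$model == "ridge"],
               tb$test_mse[tb$model == "linear"], tolerance = 1e-8)
  expect_error(linear_baselines(lin, "aform_class"), "regression")
})

test_that("importance traces normalize and unused features carry zero weight", {
  m <- tiny_radius_model()
  for (kind in c("gain", "weight")) {
    tr <- importance_trace(m, kind)
    expect_equal(sum(tr$importance), 1, tolerance = 1e-9)
    expect_true(all(tr$importance >= 0))
    expect_length(tr$q, 191)
  }
  # a feature outside every decision rule has zero weight-importance
  imp <- xgboost::xgb.importance(model = m$booster)
  unused <- setdiff(sprintf("q_%.3f", m$qgrid), imp$Feature)
  if (length(unused)) {
    tr <- importance_trace(m, "weight")
    expect_true(all(tr$importance[sprintf("q_%.3f", tr$q) %in% unused] == 0))
  }
  expect_error(importance_trace(list(), "gain"), "waxs_model")
})

test_that("prediction enforces the feature dimension", {
  m <- tiny_radius_model()
  X <- tiny_dataset()$features
  expect_error(predict(m, X[, 1:100]), "resampling must be explicit")
  p <- predict(m, X[1:3, ])
  expect_length(p, 3)
})

test_that("variant training produces the five documented variants", {
  ds <- tiny_dataset()
  cfg <- training_config(n_trees_final = 40, early_stopping_patience = 15,
                         seed = 4)
  vs <- train_variants(ds, "radius", cfg)
  expect_named(vs, c("noise_free", "noisy", "sparse", "dense", "random"))
  expect_equal(vs$sparse$n_features, 100)
  expect_equal(vs$dense$n_features, 400)
  expect_equal(vs$noise_free$n_features, 191)
  # the control on randomized labels must be much worse than the real model
  expect_gt(vs$random$metrics$value[3], vs$noise_free$metrics$value[3])
})

test_that("the Shannon channel count follows q_max * D_max / pi", {
  expect_equal(shannon_channels(30, 0.95), 0.95 * 30 / pi)
  ds <- tiny_dataset()
  expect_gt(ds$d_max, 25)
  expect_lt(ds$d_max, 50)
})

test_that("model bundles survive a save/load round trip", {
  m <- tiny_radius_model()
  dir <- withr::local_tempdir()
  save_model_bundle(m, dir)
  m2 <- load_model_bundle(dir)
  X <- tiny_dataset()$features[1:5, ]
  expect_equal(predict(m2, X), predict(m, X), tolerance = 1e-12)
  expect_equal(m2$metrics$value, m$metrics$value)
  expect_equal(m2$qgrid, m$qgrid)
})
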