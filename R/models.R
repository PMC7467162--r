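# Gradient-boosted tree models: one regressor per continuous descriptor and
# a 12-class classifier for the A-form fraction, plus the training variants,
# grouped cross-validation, learning/sampling/noise studies, linear
# baselines and q-space importance traces.

#' Training configuration
#'
#' Centralized hyperparameters for the boosted ensembles. Defaults: squared
#' error / multiclass cross-entropy objectives, learning rate 0.1, tree
#' depth 6, L2 weight penalty 1, L1 penalty 0, no per-leaf penalty, early
#' stopping after 50 stagnant rounds, 750 trees for cross-validation and
#' 7500 for final training.
#'
#' @param n_trees_cv Boosting rounds used in cross-validation.
#' @param n_trees_final Maximum boosting rounds for final models (early
#'   stopping usually halts sooner).
#' @param learning_rate Shrinkage per round.
#' @param max_depth Maximum tree depth.
#' @param reg_lambda,reg_alpha L2 and L1 penalties on leaf weights.
#' @param gamma Penalty per additional leaf.
#' @param subsample,colsample_bytree Row and feature subsampling rates per
#'   tree (stochastic boosting; 1 disables).
#' @param early_stopping_patience Rounds without validation improvement
#'   before stopping.
#' @param seed Integer seed passed to the tree learner.
#' @return A list of class `training_config`.
#' @export
training_config <- function(n_trees_cv = 750, n_trees_final = 7500,
                            learning_rate = 0.1, max_depth = 6,
                            reg_lambda = 1, reg_alpha = 0, gamma = 0,
                            subsample = 1, colsample_bytree = 1,
                            early_stopping_patience = 50, seed = 1L) {
  if (n_trees_cv < 1 || n_trees_final < 1) abort("Tree counts must be positive.")
  if (early_stopping_patience < 1) abort("`early_stopping_patience` must be positive.")
  if (subsample <= 0 || subsample > 1 || colsample_bytree <= 0 ||
      colsample_bytree > 1) {
    abort("Subsampling rates must lie in (0, 1].")
  }
  structure(list(n_trees_cv = n_trees_cv, n_trees_final = n_trees_final,
                 learning_rate = learning_rate, max_depth = max_depth,
                 reg_lambda = reg_lambda, reg_alpha = reg_alpha,
                 gamma = gamma, subsample = subsample,
                 colsample_bytree = colsample_bytree,
                 early_stopping_patience = early_stopping_patience,
                 seed = as.integer(seed)),
            class = "training_config")
}

task_for <- function(descriptor) {
  if (!descriptor %in% .waxs_descriptors) {
    abort(sprintf("`descriptor` must be one of: %s.",
                  paste(.waxs_descriptors, collapse = ", ")))
  }
  if (descriptor == "aform_class") "classification" else "regression"
}

xgb_params <- function(config, task) {
  p <- list(eta = config$learning_rate, max_depth = config$max_depth,
            lambda = config$reg_lambda, alpha = config$reg_alpha,
            gamma = config$gamma,
            subsample = config$subsample %||% 1,
            colsample_bytree = config$colsample_bytree %||% 1,
            nthread = 1, seed = config$seed,
            tree_method = "hist")
  if (task == "classification") {
    # early stopping tracks classification error, the metric of interest
    c(p, list(objective = "multi:softprob", num_class = 12,
              eval_metric = "merror"))
  } else {
    c(p, list(objective = "reg:squarederror", eval_metric = "rmse"))
  }
}

predict_xgb <- function(booster, X, task) {
  p <- predict(booster, X)
  if (task == "classification") max.col(p) - 1L else as.numeric(p)
}

# MSE for regression, classification error (1 - accuracy) for the
# classifier; lower is better for both.
task_metric <- function(pred, y, task) {
  if (task == "classification") mean(pred != y) else mean((pred - y)^2)
}

fit_booster <- function(Xtr, ytr, config, task, nrounds,
                        Xva = NULL, yva = NULL, early_stop = TRUE) {
  dtr <- xgboost::xgb.DMatrix(Xtr, label = ytr)
  evals <- list(train = dtr)
  if (!is.null(Xva)) {
    evals$validation <- xgboost::xgb.DMatrix(Xva, label = yva)
  }
  xgboost::xgb.train(
    params = xgb_params(config, task), data = dtr, nrounds = nrounds,
    evals = evals,
    early_stopping_rounds = if (early_stop && !is.null(Xva))
      config$early_stopping_patience else NULL,
    verbose = 0
  )
}

#' Train a boosted model for one descriptor
#'
#' Fits a gradient-boosted tree ensemble on the train rows, early-stopped on
#' the validation rows, and evaluates once on the held-out test rows after
#' checking the frozen test hash. Deterministic given the seed and
#' configuration. Continuous descriptors use a squared-error objective; the
#' A-form class uses softmax over 12 classes.
#'
#' @param dataset A split-tagged `swaxs_dataset`.
#' @param descriptor One of `"radius"`, `"twist"`, `"rise"`,
#'   `"major_groove_width"`, `"aform_class"`.
#' @param config A [training_config()].
#' @return A `waxs_model`: the booster plus metrics (per-split MSE or
#'   classification error, test R-squared / accuracy), a confusion matrix
#'   (native for the classifier, over 10 equal-width label bins for
#'   regressors), the q grid and the configuration.
#' @export
train_descriptor_model <- function(dataset, descriptor,
                                   config = training_config()) {
  task <- task_for(descriptor)
  assert_test_intact(dataset)
  y <- dataset$labels[[descriptor]]
  sp <- dataset$split
  itr <- sp == "train"; iva <- sp == "validation"; ite <- sp == "test"
  if (!any(itr) || !any(iva) || !any(ite)) {
    abort("Dataset must contain train, validation and test rows.")
  }
  X <- dataset$features
  booster <- fit_booster(X[itr, , drop = FALSE], y[itr], config, task,
                         nrounds = config$n_trees_final,
                         Xva = X[iva, , drop = FALSE], yva = y[iva])
  pr <- lapply(list(train = itr, validation = iva, test = ite), function(i) {
    predict_xgb(booster, X[i, , drop = FALSE], task)
  })
  metrics <- tibble(
    split = c("train", "validation", "test"),
    metric = if (task == "classification") "classification_error" else "mse",
    value = c(task_metric(pr$train, y[itr], task),
              task_metric(pr$validation, y[iva], task),
              task_metric(pr$test, y[ite], task))
  )
  if (task == "classification") {
    score <- 1 - metrics$value[3]           # test accuracy
    confusion <- table(factor(y[ite], levels = 0:11),
                       factor(pr$test, levels = 0:11))
  } else {
    score <- 1 - metrics$value[3] / var(y[ite])   # test R-squared
    brks <- seq(min(y), max(y), length.out = 11)
    cutf <- function(v) cut(v, brks, include.lowest = TRUE)
    confusion <- table(cutf(y[ite]), cutf(pmin(pmax(pr$test, min(y)), max(y))))
  }
  structure(list(booster = booster, descriptor = descriptor, task = task,
                 qgrid = dataset$qgrid, config = config, metrics = metrics,
                 test_score = score,
                 test_label_variance = var(y[ite]),
                 best_iteration = as.integer(xgboost::xgb.attr(booster, "best_iteration") %||% NA),
                 n_features = ncol(X)),
            class = "waxs_model")
}

#' @export
print.waxs_model <- function(x, ...) {
  cat(sprintf("<waxs_model> %s (%s), %d q features\n",
              x$descriptor, x$task, x$n_features))
  v <- setNames(x$metrics$value, x$metrics$split)
  lab <- if (x$task == "classification") "error" else "MSE"
  cat(sprintf("  %s train %.4g | validation %.4g | test %.4g | test %s %.3f\n",
              lab, v["train"], v["validation"], v["test"],
              if (x$task == "classification") "accuracy" else "R2",
              x$test_score))
  invisible(x)
}

#' Predict from a trained descriptor model
#'
#' @param object A `waxs_model`.
#' @param newdata Feature matrix of log10 intensities on the model's q grid.
#' @param ... Unused.
#' @return Numeric predictions (regression) or integer classes 0..11.
#' @export
predict.waxs_model <- function(object, newdata, ...) {
  if (ncol(newdata) != object$n_features) {
    abort(sprintf("Feature dimension %d does not match the model's q grid (%d points); resampling must be explicit.",
                  ncol(newdata), object$n_features))
  }
  predict_xgb(object$booster, newdata, object$task)
}

#' @export
glance.waxs_model <- function(x, ...) {
  v <- setNames(x$metrics$value, x$metrics$split)
  tibble(descriptor = x$descriptor, task = x$task,
         train = unname(v["train"]), validation = unname(v["validation"]),
         test = unname(v["test"]),
         test_score = x$test_score,
         best_iteration = x$best_iteration)
}

#' @export
tidy.waxs_model <- function(x, kind = "gain", ...) {
  importance_trace(x, kind = kind)
}

#' Train the five model variants for one descriptor
#'
#' `noise_free` uses the dataset as assembled; `noisy` adds 5 percent
#' multiplicative Gaussian noise to the training intensities (S/N = 20);
#' `sparse` and `dense` resample the profiles to 100 and 400 uniformly
#' spaced q points; `random` randomizes the labels within their observed
#' domains as a featurelessness control.
#'
#' @inheritParams train_descriptor_model
#' @return Named list of five `waxs_model`s.
#' @export
train_variants <- function(dataset, descriptor, config = training_config()) {
  list(
    noise_free = train_descriptor_model(dataset, descriptor, config),
    noisy = train_descriptor_model(
      add_noise(dataset, 0.05, seed = config$seed, rows = "train"),
      descriptor, config),
    sparse = train_descriptor_model(resample_qgrid(dataset, 100),
                                    descriptor, config),
    dense = train_descriptor_model(resample_qgrid(dataset, 400),
                                   descriptor, config),
    random = train_descriptor_model(randomize_labels(dataset, seed = config$seed),
                                    descriptor, config)
  )
}

#' Conformation-grouped k-fold cross-validation
#'
#' Folds partition conformations (never rows), consistent with the
#' conformation-grouped train/validation/test split. Each fold's model is
#' trained for `n_trees_cv` rounds on the remaining folds and scored on the
#' held-out fold. Test-tagged rows, when present, are excluded entirely.
#'
#' @inheritParams train_descriptor_model
#' @param k Number of folds.
#' @return A list: `fold_metrics` (numeric, length `k`), `mean`, `sd`,
#'   `folds` (tibble mapping conformation ids to folds), `metric` name.
#' @export
cross_validate <- function(dataset, descriptor, k = 10,
                           config = training_config()) {
  task <- task_for(descriptor)
  keep <- if (is.null(dataset$split)) rep(TRUE, nrow(dataset$features))
          else dataset$split != "test"
  ids <- unique(dataset$labels$conformation_id[keep])
  if (k > length(ids)) abort("`k` exceeds the number of conformations.")
  shuffled <- with_seed(config$seed, sample(ids))
  fold_of <- setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
  row_fold <- fold_of[dataset$labels$conformation_id]
  y <- dataset$labels[[descriptor]]
  X <- dataset$features
  fm <- vapply(seq_len(k), function(f) {
    itr <- keep & !is.na(row_fold) & row_fold != f
    ite <- keep & !is.na(row_fold) & row_fold == f
    booster <- fit_booster(X[itr, , drop = FALSE], y[itr], config, task,
                           nrounds = config$n_trees_cv, early_stop = FALSE)
    task_metric(predict_xgb(booster, X[ite, , drop = FALSE], task), y[ite], task)
  }, numeric(1))
  list(fold_metrics = fm, mean = mean(fm), sd = sd(fm),
       folds = tibble(conformation_id = names(fold_of),
                      fold = unname(fold_of)),
       metric = if (task == "classification") "classification_error" else "mse")
}

#' Learning curve: test metric versus training-set size
#'
#' Trains on nested random subsets of the training conformations (sizes
#' given in profiles) and evaluates each model on the fixed test rows.
#'
#' @inheritParams train_descriptor_model
#' @param sizes Ascending numbers of training profiles.
#' @param seeds Integer vector; the subsampling is repeated per seed.
#' @return Tibble `size`, `seed`, `test_metric`.
#' @export
learning_curve <- function(dataset, descriptor, sizes,
                           config = training_config(), seeds = 1L) {
  if (is.unsorted(sizes)) abort("`sizes` must be ascending.")
  task <- task_for(descriptor)
  assert_test_intact(dataset)
  n_cond <- length(unique(dataset$labels$condition_id))
  tr_ids <- unique(dataset$labels$conformation_id[dataset$split == "train"])
  y <- dataset$labels[[descriptor]]
  X <- dataset$features
  iva <- dataset$split == "validation"; ite <- dataset$split == "test"
  purrr::map_dfr(seeds, function(sd_) {
    ord <- with_seed(sd_, sample(tr_ids))
    purrr::map_dfr(sizes, function(sz) {
      n_conf <- min(length(ord), max(1, round(sz / n_cond)))
      itr <- dataset$labels$conformation_id %in% ord[seq_len(n_conf)]
      booster <- fit_booster(X[itr, , drop = FALSE], y[itr], config, task,
                             nrounds = config$n_trees_final,
                             Xva = X[iva, , drop = FALSE], yva = y[iva])
      tibble(size = sz, seed = sd_,
             test_metric = task_metric(
               predict_xgb(booster, X[ite, , drop = FALSE], task), y[ite], task))
    })
  })
}

#' Shannon channel count of a scattering profile
#'
#' `n_s = q_max * D_max / pi`: the number of independent information
#' channels in a curve measured to `q_max` for a particle of maximum
#' dimension `D_max`.
#'
#' @param d_max Maximum intramolecular distance, Angstrom.
#' @param q_max Maximum momentum transfer, inverse Angstrom.
#' @return Channel count (not rounded).
#' @export
shannon_channels <- function(d_max, q_max = 0.95) q_max * d_max / pi

#' Under-sampling study: test metric versus q-resolution
#'
#' Resamples the dataset to each requested number of q points, trains, and
#' evaluates on the test rows. The ensemble's Shannon channel count
#' (`q_max * D_max / pi`) is reported with the trace.
#'
#' @inheritParams train_descriptor_model
#' @param n_points_list Numbers of q points to scan.
#' @return A list: `trace` (tibble `n_points`, `test_metric`) and
#'   `shannon_channels`.
#' @export
undersampling_study <- function(dataset, descriptor, n_points_list,
                                config = training_config()) {
  trace <- purrr::map_dfr(n_points_list, function(np) {
    m <- train_descriptor_model(resample_qgrid(dataset, np), descriptor, config)
    tibble(n_points = np, test_metric = m$metrics$value[3])
  })
  list(trace = trace,
       shannon_channels = shannon_channels(dataset$d_max,
                                           max(dataset$qgrid)))
}

#' Noise study: metrics versus training-noise level
#'
#' Adds multiplicative Gaussian noise at each level to the training rows
#' (validation and test rows stay clean), trains, and records train,
#' validation and test metrics; repeated per seed.
#'
#' @inheritParams train_descriptor_model
#' @param levels Relative noise levels in `[0, 1)`.
#' @param seeds Integer vector of noise-draw seeds.
#' @return Tibble `level`, `seed`, `train_metric`, `val_metric`,
#'   `test_metric`.
#' @export
noise_study <- function(dataset, descriptor, levels = c(0.07, 0.15, 0.3),
                        config = training_config(), seeds = 1L) {
  if (any(levels < 0 | levels >= 1)) abort("`levels` must lie in [0, 1).")
  purrr::map_dfr(seeds, function(sd_) {
    purrr::map_dfr(levels, function(lv) {
      ds2 <- add_noise(dataset, lv, seed = sd_, rows = "train")
      m <- train_descriptor_model(ds2, descriptor, config)
      v <- setNames(m$metrics$value, m$metrics$split)
      tibble(level = lv, seed = sd_,
             train_metric = unname(v["train"]),
             val_metric = unname(v["validation"]),
             test_metric = unname(v["test"]))
    })
  })
}

#' Linear baselines for a regression descriptor
#'
#' Unregularized linear regression (least squares), closed-form ridge
#' regression (penalty chosen on the validation rows) and the LASSO (glmnet
#' path, penalty chosen on the validation rows), all under the same split
#' as the boosted models. Classification descriptors are rejected.
#'
#' @inheritParams train_descriptor_model
#' @param ridge_lambdas Candidate L2 penalties for ridge.
#' @return Tibble `model`, `lambda`, `train_mse`, `val_mse`, `test_mse`.
#' @export
linear_baselines <- function(dataset, descriptor,
                             ridge_lambdas = 10^seq(-4, 3, length.out = 15)) {
  if (task_for(descriptor) == "classification") {
    abort("Linear baselines apply to regression descriptors only.")
  }
  assert_test_intact(dataset)
  y <- dataset$labels[[descriptor]]
  X <- dataset$features
  itr <- dataset$split == "train"; iva <- dataset$split == "validation"
  ite <- dataset$split == "test"
  xm <- colMeans(X[itr, , drop = FALSE]); ym <- mean(y[itr])
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  mse3 <- function(pred) c(train = mean((pred[itr] - y[itr])^2),
                           val = mean((pred[iva] - y[iva])^2),
                           test = mean((pred[ite] - y[ite])^2))

  ridge_fit <- function(lambda) {
    XtX <- crossprod(Xc[itr, , drop = FALSE])
    beta <- solve(XtX + diag(lambda, ncol(Xc)),
                  crossprod(Xc[itr, , drop = FALSE], yc[itr]))
    as.numeric(Xc %*% beta) + ym
  }
  # unregularized least squares via pivoted QR (rank-deficiency tolerant)
  fit0 <- stats::lm.fit(Xc[itr, , drop = FALSE], yc[itr])
  beta0 <- ifelse(is.na(fit0$coefficients), 0, fit0$coefficients)
  ols_pred <- as.numeric(Xc %*% beta0) + ym
  m_ols <- mse3(ols_pred)

  ridge_val <- vapply(ridge_lambdas,
                      function(l) mean((ridge_fit(l)[iva] - y[iva])^2),
                      numeric(1))
  l_r <- ridge_lambdas[which.min(ridge_val)]
  m_ridge <- mse3(ridge_fit(l_r))

  fit_l <- glmnet::glmnet(X[itr, , drop = FALSE], y[itr], alpha = 1)
  pv <- predict(fit_l, X[iva, , drop = FALSE])
  j <- which.min(colMeans((pv - y[iva])^2))
  pred_l <- as.numeric(predict(fit_l, X, s = fit_l$lambda[j]))
  m_lasso <- mse3(pred_l)

  tibble(model = c("linear", "ridge", "lasso"),
         lambda = c(0, l_r, fit_l$lambda[j]),
         train_mse = c(m_ols["train"], m_ridge["train"], m_lasso["train"]),
         val_mse = c(m_ols["val"], m_ridge["val"], m_lasso["val"]),
         test_mse = c(m_ols["test"], m_ridge["test"], m_lasso["test"]))
}

#' Feature-importance trace in q-space
#'
#' Per-q normalized importance of a trained model. `"gain"` totals the loss
#' improvement contributed by splits on each q point; `"weight"` counts how
#' often each q point appears in a decision rule. Features never used by
#' any tree carry zero importance; each trace sums to 1.
#'
#' @param model A trained `waxs_model`.
#' @param kind `"gain"` or `"weight"`.
#' @return A tibble `q`, `importance`, `kind`, `descriptor` of class
#'   `waxs_importance`.
#' @export
importance_trace <- function(model, kind = c("gain", "weight")) {
  kind <- match.arg(kind)
  if (!inherits(model, "waxs_model")) abort("`model` must be a trained `waxs_model`.")
  imp <- xgboost::xgb.importance(model = model$booster)
  col <- if (kind == "gain") "Gain" else "Frequency"
  full <- tibble(feature = sprintf("q_%.3f", model$qgrid), q = model$qgrid)
  tr <- left_join(full, tibble(feature = imp$Feature, raw = imp[[col]]),
                  by = "feature")
  tr$raw[is.na(tr$raw)] <- 0
  out <- tibble(q = tr$q, importance = tr$raw / sum(tr$raw),
                kind = kind, descriptor = model$descriptor)
  class(out) <- c("waxs_importance", class(out))
  out
}
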