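# Shared fixtures, built in code and cached for the session.

.waxs_test_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .waxs_test_cache)) {
    assign(key, builder(), envir = .waxs_test_cache)
  }
  get(key, envir = .waxs_test_cache)
}

# A small split dataset shared by model-level tests.
tiny_dataset <- function() {
  cached("tiny_dataset", function() {
    ens <- sample_ensemble(80, seed = 301)
    split_by_conformation(assemble_dataset(ens), seed = 302)
  })
}

tiny_config <- function(...) {
  training_config(n_trees_final = 150, n_trees_cv = 40,
                  early_stopping_patience = 25, seed = 11, ...)
}

tiny_radius_model <- function() {
  cached("tiny_radius_model", function() {
    train_descriptor_model(tiny_dataset(), "radius", tiny_config())
  })
}

# A fabricated dataset with arbitrary features/labels, for split and
# noise bookkeeping tests that do not need real scattering.
fake_dataset <- function(n_conf, n_cond = 9, n_q = 5, label_fun = NULL,
                         seed = 1) {
  set.seed(seed)
  ids <- sprintf("c%04d", seq_len(n_conf))
  conf <- rep(ids, each = n_cond)
  cond <- rep(sprintf("cond%02d", seq_len(n_cond)), times = n_conf)
  X <- matrix(runif(n_conf * n_cond * n_q, 1, 3), n_conf * n_cond, n_q)
  q <- seq(0, 0.95, length.out = n_q)
  colnames(X) <- sprintf("q_%.3f", q)
  lab_of <- if (is.null(label_fun)) function(i) runif(4) else label_fun
  per_conf <- t(vapply(seq_len(n_conf), lab_of, numeric(4)))
  labels <- tibble::tibble(
    condition_id = cond, conformation_id = conf,
    radius = rep(per_conf[, 1], each = n_cond),
    twist = rep(per_conf[, 2], each = n_cond),
    rise = rep(per_conf[, 3], each = n_cond),
    major_groove_width = rep(per_conf[, 4], each = n_cond),
    aform_class = rep(sample(0:11, n_conf, TRUE), each = n_cond)
  )
  labels$aform_fraction <- labels$aform_class / 11
  waxsboost:::new_dataset(X, labels, q, d_max = 30)
}

rotation_matrix <- function(seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3)))
}

transform_model <- function(model, R, shift = c(0, 0, 0)) {
  xyz <- as.matrix(model$beads[, c("x", "y", "z")]) %*% R
  model$beads$x <- xyz[, 1] + shift[1]
  model$beads$y <- xyz[, 2] + shift[2]
  model$beads$z <- xyz[, 3] + shift[3]
  model
}
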