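# Labeled dataset assembly: log10 intensities under all solution conditions
# as features, structure-derived descriptors as labels, conformation-grouped
# splitting, noise injection, q-resampling and the random-label control.

.waxs_descriptors <- c("radius", "twist", "rise", "major_groove_width",
                       "aform_class")

new_dataset <- function(features, labels, qgrid, split = NULL,
                        test_hash = NULL, d_max = NA_real_) {
  structure(list(features = features, labels = labels, qgrid = qgrid,
                 split = split, test_hash = test_hash, d_max = d_max),
            class = "swaxs_dataset")
}

#' @export
print.swaxs_dataset <- function(x, ...) {
  cat(sprintf("<swaxs_dataset> %d profiles x %d q points, %d conformations\n",
              nrow(x$features), ncol(x$features),
              length(unique(x$labels$conformation_id))))
  if (!is.null(x$split)) {
    cat("  split:", paste(sprintf("%s=%d", names(table(x$split)), table(x$split)),
                          collapse = " "), "\n")
  }
  invisible(x)
}

#' Assemble a labeled SWAXS dataset from a duplex ensemble
#'
#' For every conformation the Debye profile is computed once and the five
#' descriptors are extracted once from the bead geometry; the profile is
#' then pushed through every solution condition. Features are the base-10
#' logarithms of the condition-modulated intensities (one row per
#' conformation x condition), and each conformation's label row is
#' replicated across its conditions.
#'
#' @param models List of `duplex_model`s.
#' @param conditions Condition table, default [default_conditions()] (9
#'   conditions).
#' @param qgrid Numeric q grid.
#' @param r_bead Gaussian bead width for the Debye calculation.
#' @return A `swaxs_dataset`: feature matrix (rows `conformation_id.condition_id`),
#'   row-aligned label tibble, the q grid, and the ensemble's maximum
#'   intramolecular distance `d_max` (used for Shannon channel counts).
#' @export
#' @examples
#' ds <- assemble_dataset(sample_ensemble(2, seed = 1))
#' dim(ds$features)  # 18 x 191
assemble_dataset <- function(models, conditions = default_conditions(),
                             qgrid = make_qgrid(), r_bead = 2.5) {
  q <- check_qgrid(qgrid)
  n_cond <- nrow(conditions)
  rows <- vector("list", length(models))
  labs <- vector("list", length(models))
  d_max <- 0
  for (k in seq_along(models)) {
    m <- models[[k]]
    prof <- debye_profile(m, q, r_bead = r_bead)
    d_max <- max(d_max, max(stats::dist(as.matrix(m$beads[, c("x", "y", "z")]))))
    desc <- duplex_descriptors(m)
    feat <- matrix(NA_real_, n_cond, length(q))
    for (j in seq_len(n_cond)) {
      pc <- apply_condition(prof, conditions[j, ])
      if (any(pc$intensity <= 0)) {
        abort(sprintf("Non-positive intensity for conformation '%s' under condition '%s'.",
                      m$conformation_id, conditions$condition_id[j]))
      }
      feat[j, ] <- log10(pc$intensity)
    }
    rows[[k]] <- feat
    labs[[k]] <- dplyr::bind_cols(
      tibble(condition_id = conditions$condition_id),
      desc[rep(1, n_cond), ]
    )
  }
  features <- do.call(rbind, rows)
  labels <- bind_rows(labs)
  colnames(features) <- sprintf("q_%.3f", q)
  rownames(features) <- paste(labels$conformation_id, labels$condition_id,
                              sep = ".")
  new_dataset(features, labels, q, d_max = d_max)
}

#' Split a dataset by conformation
#'
#' Conformation ids are shuffled with the seed and assigned to train,
#' validation and test sets by cumulative fraction with floor rounding, the
#' remainder going to training; all rows of a conformation share one tag.
#' A hash of the test rows (features and labels) is frozen at split time and
#' re-checked before every final evaluation, so the test set cannot drift
#' between assembly and testing.
#'
#' @param dataset A `swaxs_dataset`.
#' @param fractions Positive split fractions summing to 1, in the order
#'   train, validation, test. Default `c(0.68, 0.17, 0.15)`.
#' @param seed Integer seed for the conformation shuffle.
#' @return The dataset with `split` tags and `test_hash` set.
#' @export
split_by_conformation <- function(dataset, fractions = c(0.68, 0.17, 0.15),
                                  seed = 1L) {
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    abort("`fractions` must be three positive numbers summing to 1.")
  }
  ids <- unique(dataset$labels$conformation_id)
  n <- length(ids)
  if (n < 3) abort("Need at least as many conformations as splits.")
  shuffled <- with_seed(seed, sample(ids))
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_val - n_test
  tag <- rep(c("train", "validation", "test"), c(n_train, n_val, n_test))
  names(tag) <- shuffled
  dataset$split <- unname(tag[dataset$labels$conformation_id])
  dataset$test_hash <- hash_test_rows(dataset)
  dataset
}

hash_test_rows <- function(dataset) {
  i <- which(dataset$split == "test")
  rlang::hash(list(dataset$features[i, , drop = FALSE],
                   dataset$labels[i, .waxs_descriptors]))
}

assert_test_intact <- function(dataset) {
  if (is.null(dataset$split)) abort("Dataset has no split tags; call `split_by_conformation()` first.")
  if (!identical(hash_test_rows(dataset), dataset$test_hash)) {
    abort("Test rows have changed since the split was frozen; refusing to evaluate.")
  }
  invisible(dataset)
}

# Positive-truncated normal draws, vectorized over mean/sd (inverse CDF).
rtruncnorm_pos <- function(mean, sd) {
  out <- mean
  pos <- sd > 0
  if (any(pos)) {
    p0 <- stats::pnorm(0, mean[pos], sd[pos])
    u <- runif(sum(pos), p0, 1)
    out[pos] <- stats::qnorm(u, mean[pos], sd[pos])
  }
  out
}

#' Inject multiplicative Gaussian noise into dataset features
#'
#' Noise is applied to the intensities before the log transform:
#' `I' ~ Normal(I, (level * I)^2)`, truncated to positive values by the
#' same rule used for noisy-profile sampling (draws at or below zero are
#' replaced by draws from the positive-truncated law), so the implied
#' signal-to-noise ratio is `1 / level` (level 0.05 gives S/N = 20).
#'
#' @param dataset A `swaxs_dataset`.
#' @param relative_level Relative noise level in `[0, 1)`.
#' @param seed Integer seed.
#' @param rows Optional row subset to perturb (indices or a split tag such
#'   as `"train"`); default all rows.
#' @return The dataset with perturbed features.
#' @export
add_noise <- function(dataset, relative_level, seed = 1L, rows = NULL) {
  if (relative_level < 0 || relative_level >= 1) {
    abort("`relative_level` must lie in [0, 1).")
  }
  if (relative_level == 0) return(dataset)
  idx <- if (is.null(rows)) seq_len(nrow(dataset$features))
         else if (is.character(rows)) which(dataset$split %in% rows)
         else rows
  I <- 10^dataset$features[idx, , drop = FALSE]
  noisy <- with_seed(seed, {
    matrix(rtruncnorm_pos(as.numeric(I), relative_level * as.numeric(I)),
           nrow(I), ncol(I))
  })
  dataset$features[idx, ] <- log10(noisy)
  if (!is.null(dataset$split)) dataset$test_hash <- hash_test_rows(dataset)
  dataset
}

#' Resample dataset features onto a uniform q grid
#'
#' Intensities (not their logarithms) are interpolated row-wise by cubic
#' splines onto `n_points` uniformly spaced q values over the original grid
#' range; features are the logarithms of the interpolated intensities.
#' Interpolation never extrapolates: the new grid shares the original
#' endpoints.
#'
#' @param dataset A `swaxs_dataset`.
#' @param n_points Number of q points (>= 2).
#' @return A `swaxs_dataset` on the new grid.
#' @export
resample_qgrid <- function(dataset, n_points) {
  if (n_points < 2) abort("`n_points` must be at least 2.")
  q0 <- dataset$qgrid
  qn <- seq(q0[1], q0[length(q0)], length.out = n_points)
  if (n_points == length(q0)) {
    # uniform default grid: identity
    if (max(abs(qn - q0)) < 1e-12) return(dataset)
  }
  I <- 10^dataset$features
  newf <- t(apply(I, 1, function(row) {
    log10(spline(q0, row, xout = qn, method = "fmm")$y)
  }))
  colnames(newf) <- sprintf("q_%.3f", qn)
  rownames(newf) <- rownames(dataset$features)
  dataset$features <- newf
  dataset$qgrid <- qn
  if (!is.null(dataset$split)) dataset$test_hash <- hash_test_rows(dataset)
  dataset
}

#' Randomize labels (the random-model control)
#'
#' Replaces each continuous label column by uniform draws over its observed
#' range and the A-form class by uniform draws over the observed classes,
#' leaving features untouched. All rows of a conformation receive the same
#' randomized labels, mirroring how true labels replicate across
#' conditions.
#'
#' @param dataset A `swaxs_dataset`.
#' @param seed Integer seed.
#' @return The dataset with randomized labels.
#' @export
randomize_labels <- function(dataset, seed = 1L) {
  lab <- dataset$labels
  ids <- unique(lab$conformation_id)
  with_seed(seed, {
    for (col in setdiff(.waxs_descriptors, "aform_class")) {
      rng <- range(lab[[col]])
      per_conf <- setNames(runif(length(ids), rng[1], rng[2]), ids)
      lab[[col]] <- unname(per_conf[lab$conformation_id])
    }
    cls <- sort(unique(lab$aform_class))
    per_conf <- setNames(sample(cls, length(ids), replace = TRUE), ids)
    lab$aform_class <- unname(per_conf[lab$conformation_id])
    lab$aform_fraction <- lab$aform_class / 11
  })
  dataset$labels <- lab
  if (!is.null(dataset$split)) dataset$test_hash <- hash_test_rows(dataset)
  dataset
}

#' Tidy a SWAXS dataset into long format
#'
#' @param x A `swaxs_dataset`.
#' @param ... Unused.
#' @return A long tibble: one row per profile x q point with labels and
#'   split tags attached.
#' @export
tidy.swaxs_dataset <- function(x, ...) {
  wide <- dplyr::bind_cols(
    x$labels,
    tibble(split = x$split %||% NA_character_),
    as_tibble(x$features)
  )
  tidyr::pivot_longer(wide, dplyr::starts_with("q_"),
                      names_to = "q", names_prefix = "q_",
                      names_transform = as.numeric,
                      values_to = "log_intensity")
}

#' @export
glance.swaxs_dataset <- function(x, ...) {
  tibble(n_profiles = nrow(x$features),
         n_conformations = length(unique(x$labels$conformation_id)),
         n_conditions = length(unique(x$labels$condition_id)),
         n_q = ncol(x$features),
         d_max = x$d_max,
         split = !is.null(x$split))
}
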