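# Monte-Carlo propagation of experimental errors through trained models:
# each point of a measured profile is treated as a draw from an independent
# normal law whose width scales with the reported error, and the resulting
# cloud of predictions is summarized by its distribution and mode.

.waxs_alpha_presets <- c(low = 0.2, medium = 1.0, high = 2.0)

resolve_alpha <- function(alpha) {
  if (is.character(alpha)) {
    if (!alpha %in% names(.waxs_alpha_presets)) {
      abort("`alpha` preset must be one of 'low', 'medium', 'high'.")
    }
    return(unname(.waxs_alpha_presets[alpha]))
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0) {
    abort("`alpha` must be a single non-negative number or a preset name.")
  }
  alpha
}

#' Sample noisy SWAXS profiles from a measured profile
#'
#' Each q point is drawn independently from a normal law centred on the
#' measured intensity with standard deviation `alpha * sigma(q)`. Draws at
#' or below zero (frequent at high q for large error levels, where the
#' plain normal law is unphysical) are replaced by draws from the
#' positive-truncated normal, so every sampled curve admits the log
#' transform. The presets low/medium/high correspond to
#' `alpha = 0.2, 1.0, 2.0`; the signal-to-noise ratio scales as `1/alpha`.
#'
#' @param profile A `swaxs_profile` with a `sigma` column (an error column
#'   is required; profiles without one are rejected).
#' @param alpha Error level: a non-negative number or `"low"`, `"medium"`,
#'   `"high"`.
#' @param n Number of sampled profiles (default 5000; a warning is issued
#'   below 1000, where distribution statistics become unreliable).
#' @param seed Integer seed.
#' @return An `n` x `K` matrix of log10 intensities (one sampled profile
#'   per row) with the q grid and alpha attached as attributes.
#' @export
sample_noisy_profiles <- function(profile, alpha, n = 5000, seed = 1L) {
  a <- resolve_alpha(alpha)
  if (all(is.na(profile$sigma))) {
    abort("Profile carries no error column; supply per-point sigma to sample noisy profiles.")
  }
  if (any(is.na(profile$sigma)) || any(profile$sigma < 0)) {
    abort("`sigma` must be non-negative at every point.")
  }
  if (n < 1) abort("`n` must be at least 1.")
  if (n < 1000) {
    warn(sprintf("Only %d sampled profiles; distribution statistics are unreliable below 1000.", n))
  }
  K <- nrow(profile)
  mu <- rep(profile$intensity, each = n)
  sdv <- rep(a * profile$sigma, each = n)
  draws <- with_seed(seed, rtruncnorm_pos(mu, sdv))
  if (any(draws <= 0)) abort("Sampling produced non-positive intensities despite truncation.")
  out <- matrix(log10(draws), n, K)
  colnames(out) <- sprintf("q_%.3f", profile$q)
  attr(out, "qgrid") <- profile$q
  attr(out, "alpha") <- a
  out
}

fd_bins <- function(x, fallback = 50) {
  iqr <- stats::IQR(x)
  if (iqr <= 0 || diff(range(x)) <= 0) return(fallback)
  h <- 2 * iqr * length(x)^(-1/3)
  max(1, ceiling(diff(range(x)) / h))
}

#' Prediction distribution over sampled noisy profiles
#'
#' Applies a trained model to every sampled profile and summarizes the
#' predictions: histogram (Freedman-Diaconis binning with a fallback of 50
#' bins), mode (centre of a maximal-count bin, ties broken toward the
#' smaller value), mean and spread. For the A-form classifier the histogram
#' is the class-frequency table and the mode is the modal class.
#'
#' @param model A trained `waxs_model`.
#' @param samples Matrix from [sample_noisy_profiles()]; its q grid must
#'   match the model's grid exactly (resampling must be explicit).
#' @param bins Optional fixed number of histogram bins.
#' @return A `waxs_prediction`: list with `descriptor`, `alpha`, `samples`
#'   (the predictions), `histogram` (tibble `lower`, `upper`, `mid`,
#'   `count`), `mode`, `mean`, `sd`.
#' @export
predict_distribution <- function(model, samples, bins = NULL) {
  qg <- attr(samples, "qgrid")
  if (is.null(qg) || length(qg) != length(model$qgrid) ||
      max(abs(qg - model$qgrid)) > 1e-9) {
    abort("Sample q grid does not match the model's grid; resample explicitly before predicting.")
  }
  preds <- predict(model, samples)
  n <- length(preds)
  if (model$task == "classification") {
    counts <- table(factor(preds, levels = 0:11))
    hist_tb <- tibble(lower = 0:11 - 0.5, upper = 0:11 + 0.5,
                      mid = as.numeric(0:11), count = as.integer(counts))
    mode <- as.numeric(names(counts)[which.max(counts)])  # first max = smallest class
  } else {
    nb <- bins %||% fd_bins(preds)
    brks <- seq(min(preds), max(preds), length.out = nb + 1)
    if (length(unique(brks)) < 2) brks <- c(preds[1] - 0.5, preds[1] + 0.5)
    ct <- hist(preds, breaks = brks, plot = FALSE)
    hist_tb <- tibble(lower = utils::head(ct$breaks, -1),
                      upper = utils::tail(ct$breaks, -1),
                      mid = ct$mids, count = ct$counts)
    mode <- hist_tb$mid[which.max(hist_tb$count)]  # first max = smaller value
  }
  structure(list(descriptor = model$descriptor,
                 alpha = attr(samples, "alpha"),
                 samples = preds, histogram = hist_tb,
                 mode = mode, mean = mean(preds), sd = sd(preds)),
            class = "waxs_prediction")
}

#' @export
print.waxs_prediction <- function(x, ...) {
  cat(sprintf("<waxs_prediction> %s at alpha = %g: mode %.4g, mean %.4g, sd %.4g (n = %d)\n",
              x$descriptor, x$alpha, x$mode, x$mean, x$sd, length(x$samples)))
  invisible(x)
}

#' @export
tidy.waxs_prediction <- function(x, ...) {
  dplyr::mutate(x$histogram, descriptor = x$descriptor, alpha = x$alpha)
}

#' @export
glance.waxs_prediction <- function(x, ...) {
  tibble(descriptor = x$descriptor, alpha = x$alpha, n = length(x$samples),
         mode = x$mode, mean = x$mean, sd = x$sd)
}

#' Descriptor predictions for a set of measured profiles
#'
#' Runs the noisy-sampling and distribution-summary pipeline for every
#' profile and every supplied descriptor model, returning a tidy summary
#' table (mode, mean, spread per descriptor per profile, with the error
#' level used).
#'
#' @param models Named list of trained `waxs_model`s.
#' @param profiles Named list of `swaxs_profile`s carrying `sigma`.
#' @param alpha Error level or preset; see [sample_noisy_profiles()].
#' @param n Sampled profiles per input.
#' @param seed Integer seed.
#' @return A tibble: `profile`, `descriptor`, `alpha`, `mode`, `mean`, `sd`.
#' @export
predict_conditions_report <- function(models, profiles, alpha = "medium",
                                      n = 5000, seed = 1L) {
  if (is.null(names(profiles))) names(profiles) <- sprintf("profile%d", seq_along(profiles))
  purrr::imap_dfr(profiles, function(prof, pname) {
    smp <- sample_noisy_profiles(prof, alpha, n = n, seed = seed)
    purrr::imap_dfr(models, function(m, mname) {
      pd <- predict_distribution(m, smp)
      tibble(profile = pname, descriptor = pd$descriptor, alpha = pd$alpha,
             mode = pd$mode, mean = pd$mean, sd = pd$sd)
    })
  })
}
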