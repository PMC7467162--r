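# Debye-equation scattering on a fixed momentum-transfer grid, a parametric
# solution-condition model standing in for explicit solvent/ion modelling,
# and the additive-offset buffer-subtraction correction with propagated
# errors.

#' Momentum-transfer grid
#'
#' Inclusive-endpoint grid of q values. The default spans 0.000-0.950
#' inverse Angstrom at 0.005 spacing: 191 points.
#'
#' @param qmin,qmax Grid endpoints, inverse Angstrom (`qmin < qmax`).
#' @param spacing Grid spacing (> 0); must divide the range exactly.
#' @return Numeric vector of q values.
#' @export
#' @examples
#' length(make_qgrid())  # 191
make_qgrid <- function(qmin = 0, qmax = 0.95, spacing = 0.005) {
  if (qmin >= qmax) abort("`qmin` must be smaller than `qmax`.")
  if (spacing <= 0) abort("`spacing` must be positive.")
  n <- (qmax - qmin) / spacing
  if (abs(n - round(n)) > 1e-8) {
    abort(sprintf("Spacing %g does not divide the range [%g, %g] exactly.",
                  spacing, qmin, qmax))
  }
  qmin + spacing * seq(0, round(n))
}

check_qgrid <- function(q) {
  if (!is.numeric(q) || length(q) < 2 || any(diff(q) <= 0) || any(!is.finite(q))) {
    abort("q grid must be a strictly increasing finite numeric vector.")
  }
  q
}

#' Construct a SWAXS profile
#'
#' Bundles a q grid, intensities and optional per-point errors into the
#' profile object used throughout the package (a tibble with columns `q`,
#' `intensity`, `sigma` plus identity attributes). Use [read_profile()] for
#' the 3-column text interchange format.
#'
#' @param q Strictly increasing momentum-transfer grid (inverse Angstrom).
#' @param intensity Positive intensities, same length as `q`.
#' @param sigma Optional per-point errors (NA when absent).
#' @param conformation_id,condition Identity metadata.
#' @return A `swaxs_profile`.
#' @export
#' @examples
#' p <- swaxs_profile(make_qgrid(0, 0.1, 0.05), c(100, 90, 80))
swaxs_profile <- function(q, intensity, sigma = NA_real_,
                          conformation_id = NA_character_,
                          condition = "experimental") {
  check_qgrid(q)
  if (length(intensity) != length(q)) abort("`intensity` must match `q` in length.")
  if (!all(is.na(sigma)) && (length(sigma) != 1 && length(sigma) != length(q))) {
    abort("`sigma` must be NA, scalar, or match `q` in length.")
  }
  if (!all(is.na(sigma)) && any(sigma < 0, na.rm = TRUE)) {
    abort("`sigma` must be non-negative.")
  }
  new_profile(q, intensity, sigma, conformation_id, condition)
}

new_profile <- function(q, intensity, sigma = NA_real_,
                        conformation_id = NA_character_,
                        condition = "theoretical") {
  out <- tibble(q = q, intensity = intensity, sigma = sigma)
  class(out) <- c("swaxs_profile", class(out))
  attr(out, "conformation_id") <- conformation_id
  attr(out, "condition") <- condition
  out
}

#' Debye-equation scattering profile of a duplex model
#'
#' Orientationally averaged intensity
#' \deqn{I(q) = \sum_i \sum_j f_i(q) f_j(q)\, \mathrm{sinc}(q d_{ij}),}
#' with \eqn{\mathrm{sinc}(x) = \sin(x)/x}, \eqn{\mathrm{sinc}(0) = 1}, and a
#' Gaussian bead form factor \eqn{f_i(q) = Z_i \exp(-(q\,r_\mathrm{bead})^2/2)}
#' where \eqn{Z_i} is the bead electron count. The pair sum is evaluated
#' exactly over all bead pairs (72 beads); at `q = 0` the intensity equals
#' the squared total electron count times the form-factor envelope (which is
#' 1 there).
#'
#' @param model A `duplex_model`.
#' @param qgrid Numeric q grid (inverse Angstrom), e.g. [make_qgrid()].
#' @param r_bead Gaussian bead width in Angstrom (default 2.5); `0` gives
#'   point scatterers.
#' @return A `swaxs_profile` tibble (columns `q`, `intensity`, `sigma`) with
#'   the conformation id and condition `"theoretical"` attached as
#'   attributes.
#' @export
#' @examples
#' prof <- debye_profile(canonical_aform(), make_qgrid())
#' prof$intensity[1] == sum(canonical_aform()$beads$electrons)^2
debye_profile <- function(model, qgrid = make_qgrid(), r_bead = 2.5) {
  if (!inherits(model, "duplex_model")) abort("`model` must be a `duplex_model`.")
  q <- check_qgrid(qgrid)
  xyz <- as.matrix(model$beads[, c("x", "y", "z")])
  el <- model$beads$electrons
  if (nrow(xyz) == 0) abort("Empty model: no beads to scatter.")
  if (any(el <= 0)) abort("All bead electron counts must be positive.")

  d <- as.matrix(stats::dist(xyz))
  iu <- upper.tri(d)
  dv <- d[iu]
  w <- (el %o% el)[iu]
  qd <- outer(q, dv)
  s <- sin(qd) / qd
  s[qd == 0] <- 1
  S <- 2 * as.numeric(s %*% w) + sum(el^2)
  I <- exp(-(q * r_bead)^2) * S
  new_profile(q, I, conformation_id = model$conformation_id)
}

#' The nine documented solution conditions
#'
#' 30, 50, 100, 200 and 500 mM KCl plus 0.25, 0.50, 1.00 and 5.00 mM
#' MgCl2. Each condition carries a contrast modulation amplitude
#' (`contrast_epsilon`, dimensionless, applied to a low-q Gaussian envelope)
#' and an additive background expressed as a fraction of the profile
#' intensity at the highest q point (`offset_frac`). The amplitudes are
#' calibrated so that fitted additive offsets between condition pairs stay
#' below 10 percent of the intensity at q_max: because the intensity spans
#' about four decades over the grid, condition-to-condition variation is
#' carried almost entirely by the additive term, and the multiplicative
#' low-q term is kept correspondingly small.
#'
#' @return A 9-row tibble: `condition_id`, `salt`, `concentration_mM`,
#'   `contrast_epsilon`, `offset_frac`.
#' @export
default_conditions <- function() {
  out <- tibble(
    salt = c(rep("KCl", 5), rep("MgCl2", 4)),
    concentration_mM = c(30, 50, 100, 200, 500, 0.25, 0.5, 1, 5),
    contrast_epsilon = c(-4e-6, -2e-6, 0, 2e-6, 4e-6,
                         -1e-6, -3e-6, -5e-6, -8e-6),
    offset_frac = c(-0.030, -0.015, 0.000, 0.010, 0.020,
                    -0.020, -0.005, 0.015, 0.030)
  )
  out$condition_id <- sprintf("%s_%gmM", out$salt, out$concentration_mM)
  out[, c("condition_id", "salt", "concentration_mM",
          "contrast_epsilon", "offset_frac")]
}

# Fixed smooth low-q envelope of the contrast modulation.
condition_envelope <- function(q) exp(-(q / 0.2)^2)

#' Apply a solution condition to a theoretical profile
#'
#' \deqn{I_\mathrm{cond}(q) = I(q)\,[1 + \epsilon\, g(q)] + b,}
#' with \eqn{g(q) = \exp(-(q/0.2)^2)} and additive background
#' \eqn{b = \mathrm{offset\_frac} \times I(q_\mathrm{max})}. Deterministic
#' per condition.
#'
#' @param profile A `swaxs_profile` (theoretical).
#' @param condition A `condition_id` string or a one-row slice of
#'   [default_conditions()] (or a tibble of the same shape).
#' @param conditions Condition table to resolve string ids against.
#' @return A `swaxs_profile` with the condition id attached.
#' @export
apply_condition <- function(profile, condition,
                            conditions = default_conditions()) {
  if (is.character(condition)) {
    row <- conditions[conditions$condition_id == condition, ]
    if (nrow(row) != 1) {
      abort(sprintf("Unknown condition '%s'.", condition))
    }
  } else if (is.data.frame(condition) && nrow(condition) == 1) {
    row <- condition
  } else {
    abort("`condition` must be a condition id or a one-row condition table.")
  }
  q <- profile$q
  I <- profile$intensity
  b <- row$offset_frac * I[length(I)]
  I2 <- I * (1 + row$contrast_epsilon * condition_envelope(q)) + b
  new_profile(q, I2,
              conformation_id = attr(profile, "conformation_id"),
              condition = row$condition_id)
}

#' Propagate experimental errors
#'
#' Pluggable propagation of per-point experimental errors. The default rule
#' is the identity, `sigma_prime = sigma`; an alternative rule (a function
#' of `sigma` and `snr`) may be supplied, e.g. to inflate errors where the
#' signal-to-noise ratio is poor. Only the weights of the offset fit depend
#' on the rule; its closed form does not.
#'
#' @param sigma Non-negative per-point errors.
#' @param snr Optional per-point signal-to-noise ratios (> 0 where used).
#' @param rule Optional `function(sigma, snr)` returning the propagated
#'   errors; `NULL` uses the identity.
#' @return Numeric vector `sigma_prime`.
#' @export
propagate_error <- function(sigma, snr = NULL, rule = NULL) {
  if (any(is.na(sigma)) || any(sigma < 0)) {
    abort("`sigma` must be non-negative and free of missing values.")
  }
  if (!is.null(snr) && any(snr <= 0)) {
    abort("`snr` must be positive where supplied.")
  }
  if (is.null(rule)) return(sigma)
  out <- rule(sigma, snr)
  if (length(out) != length(sigma)) abort("Propagation rule returned the wrong length.")
  out
}

#' Fit the additive buffer-subtraction offset
#'
#' The constant `c` minimizing
#' \deqn{\sum_j \frac{[I(q_j) + c - I_\mathrm{exp}(q_j)]^2}{\sigma'(q_j)^2},}
#' i.e. the \eqn{\sigma'}-weighted mean residual
#' \eqn{c = \sum_j w_j [I_\mathrm{exp}(q_j) - I(q_j)] / \sum_j w_j} with
#' \eqn{w_j = 1/\sigma'(q_j)^2}; the corrected profile is `I(q) + c`. When
#' the experiment carries no errors, uniform weights are used.
#'
#' @param theory,experiment `swaxs_profile`s on identical q grids; the
#'   experimental errors are passed through [propagate_error()].
#' @param snr Optional per-point signal-to-noise for the propagation rule.
#' @param rule Optional error-propagation rule; see [propagate_error()].
#' @return The fitted offset `c` (a single number).
#' @export
fit_offset_c <- function(theory, experiment, snr = NULL, rule = NULL) {
  if (length(theory$q) != length(experiment$q) ||
      max(abs(theory$q - experiment$q)) > 1e-9) {
    abort("`theory` and `experiment` must share an identical q grid.")
  }
  if (all(is.na(experiment$sigma))) {
    w <- rep(1, length(theory$q))
  } else {
    sp <- propagate_error(experiment$sigma, snr = snr, rule = rule)
    if (any(sp == 0)) {
      abort("Zero propagated errors give degenerate (infinite) weights; supply positive sigma.")
    }
    w <- 1 / sp^2
  }
  sum(w * (experiment$intensity - theory$intensity)) / sum(w)
}
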