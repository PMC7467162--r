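# Structural descriptor extraction from bead models. These five quantities
# (radius, mean twist, mean rise, major groove width, A-form class) are the
# supervised labels of the learning pipeline; they are always computed from
# the bead geometry, never copied from generator latents.

bead_xyz <- function(model, bead = NULL, strand = NULL) {
  b <- model$beads
  if (!is.null(bead)) b <- b[b$bead == bead, , drop = FALSE]
  if (!is.null(strand)) b <- b[b$strand == strand, , drop = FALSE]
  as.matrix(b[, c("x", "y", "z")])
}

# Base-pair centers: mean of the six beads of each bp (bp i = strand-1
# residue i + strand-2 residue 13-i).
bp_centers <- function(model) {
  b <- model$beads
  bp <- ifelse(b$strand == 1L, b$residue, 13L - b$residue)
  xyz <- as.matrix(b[, c("x", "y", "z")])
  t(vapply(1:12, function(i) colMeans(xyz[bp == i, , drop = FALSE]),
           numeric(3)))
}

# Least-squares circle center (Kasa fit) of 2-D points; exact when the
# points lie on a circle.
circle_center <- function(u) {
  x <- u[, 1]; y <- u[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  ab <- solve(crossprod(A), crossprod(A, b))
  c(ab[1], ab[2])
}

#' Fit the helical axis of a duplex model
#'
#' Two-stage fit: a principal-component line through the phosphate beads
#' initializes the axis direction, which is then refined by a cylinder fit
#' minimizing the variance of phosphate-to-axis distances (the inner circle
#' center is solved in closed form for each trial direction). For zero-jitter
#' models the phosphates lie exactly on a cylinder, so the fit recovers the
#' construction axis to optimizer precision. The direction is oriented so
#' the axial coordinate increases with base-pair index (5' to 3' of
#' strand 1); a left-handed (negative-twist) geometry is reported as an
#' error downstream, not here.
#'
#' @param model A `duplex_model`.
#' @return An object of class `helical_axis`: list with `origin` (a point on
#'   the axis), `direction` (unit vector), and the fitted mean phosphate
#'   radius `radius`.
#' @export
fit_helical_axis <- function(model) {
  if (!inherits(model, "duplex_model")) abort("`model` must be a `duplex_model`.")
  P <- bead_xyz(model, bead = "phosphate")
  if (nrow(P) < 4) abort("Degenerate bead set: too few phosphates for an axis fit.")
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  pc <- prcomp(Pc, center = FALSE)

  # Orthonormal frame with e3 = trial direction.
  frame_of <- function(d) {
    d <- d / sqrt(sum(d^2))
    a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- a - sum(a * d) * d; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(d[2] * e1[3] - d[3] * e1[2],
            d[3] * e1[1] - d[1] * e1[3],
            d[1] * e1[2] - d[2] * e1[1])
    cbind(e1, e2, d)
  }
  obj_in_frame <- function(f0) function(th) {
    d <- f0 %*% c(sin(th[1]), sin(th[2]),
                  sqrt(max(0, 1 - sin(th[1])^2 - sin(th[2])^2)))
    fr <- frame_of(d)
    u <- Pc %*% fr[, 1:2]
    cc <- circle_center(u)
    r <- sqrt((u[, 1] - cc[1])^2 + (u[, 2] - cc[2])^2)
    var(r)
  }
  # Principal directions of a one-turn helix tilt away from the true axis
  # (helical phase correlates with height), so collect several candidate
  # directions - the principal axes, the end-to-end base-pair vector (whose
  # in-plane components nearly cancel over a full turn), and a coarse
  # hemisphere scan - and refine from the best cylinder among them.
  ctrs0 <- bp_centers(model)
  e2e <- ctrs0[nrow(ctrs0), ] - ctrs0[1, ]
  golden <- pi * (3 - sqrt(5))
  ks <- seq_len(40)
  zs <- (ks - 0.5) / 40
  scan <- cbind(sqrt(1 - zs^2) * cos(golden * ks),
                sqrt(1 - zs^2) * sin(golden * ks), zs)
  cands <- rbind(t(pc$rotation), e2e / sqrt(sum(e2e^2)), scan)
  init_vals <- vapply(seq_len(nrow(cands)), function(k)
    obj_in_frame(frame_of(cands[k, ]))(c(0, 0)), numeric(1))
  f0 <- frame_of(cands[which.min(init_vals), ])
  obj <- obj_in_frame(f0)
  o <- optim(c(0, 0), obj, method = "Nelder-Mead",
             control = list(reltol = 1e-15, maxit = 2000))
  o <- optim(o$par, obj, method = "Nelder-Mead",
             control = list(reltol = 1e-15, maxit = 2000))
  th <- o$par
  d <- as.numeric(f0 %*% c(sin(th[1]), sin(th[2]),
                           sqrt(max(0, 1 - sin(th[1])^2 - sin(th[2])^2))))
  d <- d / sqrt(sum(d^2))
  fr <- frame_of(d)
  u <- Pc %*% fr[, 1:2]
  cc <- circle_center(u)
  origin <- ctr + fr[, 1] * cc[1] + fr[, 2] * cc[2]
  radius <- mean(sqrt((u[, 1] - cc[1])^2 + (u[, 2] - cc[2])^2))

  # Orient: axial coordinate must increase with bp index.
  ctrs <- bp_centers(model)
  s <- as.numeric(sweep(ctrs, 2, origin) %*% d)
  if (coef(lm(s ~ seq_along(s)))[2] < 0) d <- -d

  structure(list(origin = origin, direction = d, radius = radius),
            class = "helical_axis")
}

#' @export
print.helical_axis <- function(x, ...) {
  cat(sprintf("<helical_axis> direction (%.3f, %.3f, %.3f), phosphate radius %.3f A\n",
              x$direction[1], x$direction[2], x$direction[3], x$radius))
  invisible(x)
}

# Axis-frame coordinates: axial s, in-plane (u1, u2), azimuth, radial r.
axis_frame <- function(xyz, axis) {
  d <- axis$direction
  a <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * d) * d; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  rel <- sweep(xyz, 2, axis$origin)
  s <- as.numeric(rel %*% d)
  u1 <- as.numeric(rel %*% e1)
  u2 <- as.numeric(rel %*% e2)
  list(s = s, u1 = u1, u2 = u2,
       azimuth = atan2(u2, u1), r = sqrt(u1^2 + u2^2))
}

unwrap <- function(a) {
  d <- diff(a)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(a[1], a[1] + cumsum(d))
}

#' Helical radius of a duplex
#'
#' Mean perpendicular distance of the 24 phosphate beads to the fitted
#' helical axis.
#'
#' @param model A `duplex_model`.
#' @param axis Optional precomputed [fit_helical_axis()] result.
#' @return Radius in Angstrom.
#' @export
compute_radius <- function(model, axis = fit_helical_axis(model)) {
  fr <- axis_frame(bead_xyz(model, bead = "phosphate"), axis)
  mean(fr$r)
}

# Per-step geometry: twist (deg), rise (A), base displacement (A). Twist is
# the signed angle between successive strand-1 phosphate-to-axis vectors
# projected perpendicular to the axis; rise is the axial separation of
# successive bp centers; displacement is the mean radial distance of the
# base beads of the step's 5' base pair (bp i for step i).
step_geometry <- function(model, axis = fit_helical_axis(model)) {
  b <- model$beads
  p1 <- b[b$bead == "phosphate" & b$strand == 1L, ]
  p1 <- p1[order(p1$residue), ]
  fr1 <- axis_frame(as.matrix(p1[, c("x", "y", "z")]), axis)
  az <- unwrap(fr1$azimuth)
  twist <- diff(az) * 180 / pi

  ctrs <- bp_centers(model)
  frc <- axis_frame(ctrs, axis)
  rise <- diff(frc$s)

  bb <- b[b$bead == "base", ]
  bp <- ifelse(bb$strand == 1L, bb$residue, 13L - bb$residue)
  frb <- axis_frame(as.matrix(bb[, c("x", "y", "z")]), axis)
  disp_bp <- vapply(1:12, function(i) mean(frb$r[bp == i]), numeric(1))

  tibble(step = 1:11, twist = twist, rise = rise,
         displacement = disp_bp[1:11])
}

#' Mean helical twist and rise
#'
#' Per-step twist is the signed angle between successive base-pair
#' phosphate-to-axis vectors (strand 1) projected perpendicular to the axis;
#' per-step rise is the axial separation of successive base-pair centers.
#' Means over the 11 steps are returned. A left-handed geometry (negative
#' mean twist) is out of domain and raises an error.
#'
#' @inheritParams compute_radius
#' @return Named numeric vector `c(twist = degrees, rise = Angstrom)`.
#' @export
compute_twist_rise <- function(model, axis = fit_helical_axis(model)) {
  sg <- step_geometry(model, axis)
  if (mean(sg$twist) < 0) {
    abort("Left-handed helix detected (negative mean twist); mirror-imaged duplexes are out of domain.")
  }
  c(twist = mean(sg$twist), rise = mean(sg$rise))
}

#' Major groove width
#'
#' Raw minimal cross-strand phosphate-phosphate distance measured on
#' spline-interpolated backbone traces, restricted to the major groove. The
#' major groove side is identified from base orientation: base beads sit on
#' the minor-groove bisector, so a cross-strand segment belongs to the major
#' groove when its midpoint azimuth is opposite the local base azimuth. The
#' strand-1 scan is limited to the central base pairs (3 to 10) to avoid end
#' effects. No phosphate van der Waals diameter is subtracted: the canonical
#' A-form evaluates to 8.7 Angstrom under this convention.
#'
#' @inheritParams compute_radius
#' @param n_dense Number of dense spline samples per strand.
#' @return Width in Angstrom.
#' @export
major_groove_width <- function(model, axis = fit_helical_axis(model),
                               n_dense = 300) {
  b <- model$beads
  getP <- function(strand) {
    p <- b[b$bead == "phosphate" & b$strand == strand, ]
    bp <- if (strand == 1L) p$residue else 13L - p$residue
    p <- p[order(bp), ]
    fr <- axis_frame(as.matrix(p[, c("x", "y", "z")]), axis)
    cbind(fr$u1, fr$u2, fr$s)
  }
  P1 <- getP(1L); P2 <- getP(2L)

  t_in <- 1:12
  sp3 <- function(P, t_out) {
    cbind(spline(t_in, P[, 1], xout = t_out)$y,
          spline(t_in, P[, 2], xout = t_out)$y,
          spline(t_in, P[, 3], xout = t_out)$y)
  }
  td1 <- seq(3, 10, length.out = n_dense)
  td2 <- seq(1, 12, length.out = n_dense)
  s1 <- sp3(P1, td1)
  s2 <- sp3(P2, td2)

  # Base azimuth per bp (unwrapped), interpolated along the strand-1 trace;
  # the major-groove bisector is its opposite.
  bb <- b[b$bead == "base", ]
  bpb <- ifelse(bb$strand == 1L, bb$residue, 13L - bb$residue)
  frb <- axis_frame(as.matrix(bb[, c("x", "y", "z")]), axis)
  az_b <- vapply(1:12, function(i) {
    v1 <- mean(frb$u1[bpb == i]); v2 <- mean(frb$u2[bpb == i])
    atan2(v2, v1)
  }, numeric(1))
  az_b <- unwrap(az_b)
  psi_maj <- spline(t_in, az_b, xout = td1)$y + pi

  dx <- outer(s1[, 1], s2[, 1], "-")
  dy <- outer(s1[, 2], s2[, 2], "-")
  dz <- outer(s1[, 3], s2[, 3], "-")
  d2 <- dx^2 + dy^2 + dz^2
  mx <- outer(s1[, 1], s2[, 1], "+") / 2
  my <- outer(s1[, 2], s2[, 2], "+") / 2
  ang <- atan2(my, mx)
  on_major <- cos(sweep(ang, 1, psi_maj, "-")) > 0
  if (!any(on_major)) {
    abort("Major groove scan failed: no cross-strand segment lies on the major-groove side.")
  }
  sqrt(min(d2[on_major]))
}

#' Classify base-pair steps as A-like or B-like
#'
#' Per-step classification by nearest setpoint in (rise, base displacement)
#' space, each coordinate standardized by half the A-B setpoint gap. On
#' zero-jitter models this reproduces the generator's latent form flags
#' exactly. The class is the number of A-like steps, an integer 0..11.
#'
#' @inheritParams compute_radius
#' @return List with `flags` (logical, length 11, `TRUE` = A-like) and
#'   `class` (integer 0..11).
#' @export
classify_aform_steps <- function(model, axis = fit_helical_axis(model)) {
  sg <- step_geometry(model, axis)
  g <- .waxs_geom
  rise_scale <- abs(g$rise_bform - g$rise_aform) / 2
  disp_scale <- abs(g$disp_aform - g$disp_bform) / 2
  dA <- ((sg$rise - g$rise_aform) / rise_scale)^2 +
        ((sg$displacement - g$disp_aform) / disp_scale)^2
  dB <- ((sg$rise - g$rise_bform) / rise_scale)^2 +
        ((sg$displacement - g$disp_bform) / disp_scale)^2
  flags <- dA <= dB
  list(flags = flags, class = as.integer(sum(flags)))
}

#' Extract all five structural descriptors from a duplex model
#'
#' Fits the helical axis once and returns a one-row tibble with the helical
#' radius, mean twist, mean rise, major groove width and A-form class
#' (0..11, also reported as a fraction of 11 steps).
#'
#' @param model A `duplex_model`.
#' @return A one-row tibble: `conformation_id`, `radius`, `twist`, `rise`,
#'   `major_groove_width`, `aform_class`, `aform_fraction`.
#' @export
#' @examples
#' duplex_descriptors(canonical_aform())
duplex_descriptors <- function(model) {
  axis <- fit_helical_axis(model)
  tr <- compute_twist_rise(model, axis)
  cls <- classify_aform_steps(model, axis)
  tibble(
    conformation_id = model$conformation_id,
    radius = compute_radius(model, axis),
    twist = unname(tr["twist"]),
    rise = unname(tr["rise"]),
    major_groove_width = major_groove_width(model, axis),
    aform_class = cls$class,
    aform_fraction = cls$class / 11
  )
}

#' Descriptor table for an ensemble
#'
#' @param models List of `duplex_model`s.
#' @return A tibble with one row per model; see [duplex_descriptors()].
#' @export
ensemble_descriptors <- function(models) {
  purrr::map_dfr(models, duplex_descriptors)
}
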