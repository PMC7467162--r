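# Coarse-grained duplex generator: 12-bp RNA duplexes built on an ideal
# straight helical axis from per-step helical parameters, three beads per
# residue (phosphate, sugar, base).

# Geometric setpoints and calibration constants.
#
# A-like steps use fiber-model A-RNA values (twist 32.7 deg, rise 2.81 A).
# Non-A ("B-like") steps model the distorted geometry RNA duplexes adopt
# away from the canonical A-form - B-like in the sense of reduced base-pair
# displacement from the axis, with the unwound, axially compacted step
# geometry seen under divalent ions (rather than B-DNA fiber values, which
# would lengthen the duplex beyond the 25-30 A span of a 12-bp helix).
# Base-pair displacement is the main geometric difference between the two
# forms at bead resolution: A-form base pairs sit ~4.4 A off axis (the
# axis runs through the deep major groove), non-A pairs sit near the axis.
#
# `strand_phase_deg` is the azimuthal offset between the two phosphate
# backbones, measured across the minor-groove side where the base beads sit.
# Its default is a calibration constant: it is fixed (once) so that the
# canonical A-form duplex evaluates to a raw cross-strand phosphate-phosphate
# major groove width of 8.7 A under [major_groove_width()].
.waxs_geom <- list(
  strand_phase_deg = 245.4957733,
  radius_aform     = 9.4,
  twist_aform      = 32.7,
  rise_aform       = 2.81,
  twist_bform      = 30.0,
  rise_bform       = 2.25,
  disp_aform       = 4.4,
  disp_bform       = 0.8,
  sugar_dr         = 2.6,   # sugar bead sits this much inside the P radius
  sugar_dang_deg   = 20,    # azimuthal offset of sugar from its phosphate
  base_dang_deg    = 14     # half-splay of the two base beads about the bp bisector
)

# Electron counts per bead, by summing atomic numbers of the atoms assigned
# to each bead for RNA residue chemistry:
#   phosphate bead: P + 4 O (both bridging oxygens assigned here) = 15 + 32 = 47
#   sugar bead: in-chain ribose C5 H7 O2 (C1'-C5', O4', O2'-H; O5'/O3'
#     counted with the phosphate) = 30 + 7 + 16 = 53
#   base beads (glycosidic H removed):
#     A  C5H4N5   = 30 + 4 + 35      = 69
#     G  C5H4N5O  = 30 + 4 + 35 + 8  = 77
#     C  C4H4N3O  = 24 + 4 + 21 + 8  = 57
#     U  C4H3N2O2 = 24 + 3 + 14 + 16 = 57
.waxs_electrons <- list(
  phosphate = 47, sugar = 53,
  base = c(A = 69, G = 77, C = 57, U = 57)
)

.waxs_complement <- c(A = "U", U = "A", G = "C", C = "G")

#' Default duplex sequence
#'
#' The 12-mer used throughout: 5'-CCU CCU AAU CGC-3' annealed with its
#' reverse complement. Both strands are returned 5' to 3'; base pair `i`
#' pairs residue `i` of strand 1 with residue `13 - i` of strand 2.
#'
#' @return Character vector of length 2 (strand 1, strand 2).
#' @export
#' @examples
#' waxs_sequence()
waxs_sequence <- function() {
  s1 <- "CCUCCUAAUCGC"
  s2 <- paste(rev(.waxs_complement[strsplit(s1, "")[[1]]]), collapse = "")
  c(s1, s2)
}

check_sequence <- function(sequence) {
  if (length(sequence) == 1) {
    s1 <- toupper(sequence)
    sequence <- c(s1, paste(rev(.waxs_complement[strsplit(s1, "")[[1]]]),
                            collapse = ""))
  }
  if (length(sequence) != 2) {
    abort("`sequence` must be one strand or a pair of strands.")
  }
  sequence <- toupper(sequence)
  b1 <- strsplit(sequence[1], "")[[1]]
  b2 <- strsplit(sequence[2], "")[[1]]
  if (length(b1) != 12 || length(b2) != 12) {
    abort("Both strands must be 12 nt long for a 12-bp duplex.")
  }
  if (!all(b1 %in% names(.waxs_complement)) ||
      !all(b2 %in% names(.waxs_complement))) {
    abort("Strands may only contain A, C, G, U.")
  }
  if (!all(.waxs_complement[b1] == rev(b2))) {
    abort("Strands are not complementary (strand 2 must be the reverse complement of strand 1).")
  }
  sequence
}

#' Helical parameter set for one duplex conformation
#'
#' The latent generator parameters of a single 12-bp duplex: a phosphate
#' radius, eleven per-step twists and rises, eleven per-step form flags
#' (A-like vs B-like), and a per-bead Gaussian jitter scale.
#'
#' @param radius Phosphate distance from the helical axis, in Angstrom (> 0).
#' @param step_twist Numeric vector of 11 per-step twists in degrees, each in
#'   (0, 60).
#' @param step_rise Numeric vector of 11 per-step rises in Angstrom (> 0).
#' @param step_form Logical vector of 11 flags, `TRUE` for A-like steps.
#' @param jitter_scale Standard deviation of isotropic per-bead Gaussian
#'   positional noise, in Angstrom (>= 0).
#' @param conformation_id Identifier attached to models built from this set.
#'
#' @return An object of class `helical_params`.
#' @export
#' @examples
#' helical_params(radius = 9.4, step_twist = rep(32.7, 11),
#'                step_rise = rep(2.81, 11), step_form = rep(TRUE, 11))
helical_params <- function(radius,
                           step_twist,
                           step_rise,
                           step_form = rep(TRUE, 11),
                           jitter_scale = 0,
                           conformation_id = "conf") {
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    abort("`radius` must be a single positive number (Angstrom).")
  }
  if (length(step_twist) != 11 || length(step_rise) != 11 ||
      length(step_form) != 11) {
    abort("`step_twist`, `step_rise` and `step_form` must each have 11 entries (12-bp duplex).")
  }
  if (any(step_twist <= 0) || any(step_twist >= 60)) {
    abort("All `step_twist` values must lie in (0, 60) degrees.")
  }
  if (any(step_rise <= 0)) {
    abort("All `step_rise` values must be positive.")
  }
  if (jitter_scale < 0) {
    abort("`jitter_scale` must be non-negative.")
  }
  structure(
    list(conformation_id = as.character(conformation_id),
         radius = as.numeric(radius),
         step_twist = as.numeric(step_twist),
         step_rise = as.numeric(step_rise),
         step_form = as.logical(step_form),
         jitter_scale = as.numeric(jitter_scale)),
    class = "helical_params"
  )
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf("<helical_params> %s\n", x$conformation_id))
  cat(sprintf("  radius %.3f A | mean twist %.2f deg | mean rise %.3f A | %d/11 A-steps | jitter %.2f A\n",
              x$radius, mean(x$step_twist), mean(x$step_rise),
              sum(x$step_form), x$jitter_scale))
  invisible(x)
}

# Run `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build a coarse-grained duplex model from helical parameters
#'
#' Places 2 strands x 12 residues x 3 beads (phosphate, sugar, base) on an
#' ideal straight-axis helix defined by the cumulative per-step twist and
#' rise at the given phosphate radius. The two backbones are offset by the
#' strand phase angle; base beads sit on the minor-groove bisector at a
#' radial displacement set by each step's form flag (A-like steps use the
#' A-form displacement setpoint, others the B-like one). Finally every bead
#' is perturbed by isotropic Gaussian jitter of scale `jitter_scale`.
#'
#' @param params A [helical_params()] object.
#' @param sequence Strand pair (character vector of length 2, both 5'->3'),
#'   or a single strand whose reverse complement is used for strand 2.
#' @param seed Integer seed for the jitter draw; the build is deterministic
#'   given `(params, seed)`.
#' @param strand_phase_deg Azimuthal offset between the two phosphate
#'   backbones, in degrees, measured across the minor-groove side. The
#'   default is calibrated so that [canonical_aform()] has a major groove
#'   width of 8.7 Angstrom.
#'
#' @return An object of class `duplex_model`: a list with the bead tibble
#'   (`beads`: strand, residue, bead, x, y, z, electrons), the sequence, the
#'   conformation id and the latent parameters (retained for round-trip
#'   checks only; they are never used as supervised labels).
#' @export
#' @examples
#' p <- helical_params(9.4, rep(32.7, 11), rep(2.81, 11))
#' m <- build_duplex(p)
#' nrow(m$beads)  # 72
build_duplex <- function(params,
                         sequence = waxs_sequence(),
                         seed = 1L,
                         strand_phase_deg = .waxs_geom$strand_phase_deg) {
  if (!inherits(params, "helical_params")) {
    abort("`params` must be a `helical_params` object.")
  }
  sequence <- check_sequence(sequence)
  b1 <- strsplit(sequence[1], "")[[1]]
  b2 <- strsplit(sequence[2], "")[[1]]

  g   <- strand_phase_deg * pi / 180
  phi <- c(0, cumsum(params$step_twist)) * pi / 180
  z   <- c(0, cumsum(params$step_rise))
  # Base-pair displacement follows the form flag of the step whose 5' base
  # pair it is; bp 12 inherits the last step's flag. This keeps per-step
  # displacement an exact readout of the latent flag.
  disp_bp <- ifelse(params$step_form[c(1:11, 11)],
                    .waxs_geom$disp_aform, .waxs_geom$disp_bform)

  ds  <- .waxs_geom$sugar_dang_deg * pi / 180
  db  <- .waxs_geom$base_dang_deg * pi / 180
  rs  <- params$radius - .waxs_geom$sugar_dr
  if (rs <= 0) abort("`radius` is too small for the sugar bead offset.")

  rows <- vector("list", 12)
  for (i in 1:12) {
    a1 <- phi[i]; a2 <- phi[i] + g; am <- phi[i] + g / 2
    rows[[i]] <- tibble(
      strand  = c(1L, 1L, 1L, 2L, 2L, 2L),
      residue = c(i, i, i, 13L - i, 13L - i, 13L - i),
      bead    = rep(c("phosphate", "sugar", "base"), 2),
      x = c(params$radius * cos(a1), rs * cos(a1 + ds), disp_bp[i] * cos(am - db),
            params$radius * cos(a2), rs * cos(a2 - ds), disp_bp[i] * cos(am + db)),
      y = c(params$radius * sin(a1), rs * sin(a1 + ds), disp_bp[i] * sin(am - db),
            params$radius * sin(a2), rs * sin(a2 - ds), disp_bp[i] * sin(am + db)),
      z = z[i],
      electrons = c(.waxs_electrons$phosphate, .waxs_electrons$sugar,
                    .waxs_electrons$base[[b1[i]]],
                    .waxs_electrons$phosphate, .waxs_electrons$sugar,
                    .waxs_electrons$base[[b2[13 - i]]])
    )
  }
  beads <- bind_rows(rows)

  if (params$jitter_scale > 0) {
    jit <- with_seed(seed, matrix(rnorm(72 * 3, sd = params$jitter_scale), 72, 3))
    beads$x <- beads$x + jit[, 1]
    beads$y <- beads$y + jit[, 2]
    beads$z <- beads$z + jit[, 3]
  }

  structure(
    list(conformation_id = params$conformation_id,
         sequence = sequence,
         beads = beads,
         latent_params = params,
         strand_phase_deg = strand_phase_deg),
    class = "duplex_model"
  )
}

#' @export
print.duplex_model <- function(x, ...) {
  cat(sprintf("<duplex_model> %s: 12-bp duplex, %d beads, %d electrons\n",
              x$conformation_id, nrow(x$beads), sum(x$beads$electrons)))
  invisible(x)
}

#' Canonical A-form reference duplex
#'
#' A fiber-model A-RNA duplex: uniform twist 32.7 deg, rise 2.81 A, phosphate
#' radius 9.4 A, all steps A-flagged, zero jitter. Used as the calibration
#' reference for the major groove width convention (8.7 A raw cross-strand
#' phosphate distance).
#'
#' @inheritParams build_duplex
#' @return A `duplex_model`.
#' @export
#' @examples
#' canonical_aform()
canonical_aform <- function(sequence = waxs_sequence()) {
  p <- helical_params(
    radius = .waxs_geom$radius_aform,
    step_twist = rep(.waxs_geom$twist_aform, 11),
    step_rise = rep(.waxs_geom$rise_aform, 11),
    step_form = rep(TRUE, 11),
    jitter_scale = 0,
    conformation_id = "canonical_aform"
  )
  build_duplex(p, sequence = sequence)
}

#' Default parameter ranges for the synthetic ensemble
#'
#' Sampling windows emulating the conformational diversity of a
#' molecular-dynamics duplex ensemble. Helical fluctuations in duplex MD
#' are dominated by collective modes (global unwinding or over-winding,
#' axial stretching or compression), so per-step twist and rise decompose
#' into a conformation-level collective shift (uniform within
#' `*_collective_halfwidth` of the form setpoint) plus small independent
#' per-step residuals (uniform within `*_step_halfwidth`); per-bead jitter
#' adds residual local disorder on a smaller scale still. Form flags are
#' drawn independently per step with probability `p_aform` of being A-like.
#' The rise windows keep ensemble lengths (11 x mean rise) in the
#' 25-30 Angstrom span typical of a 12-bp duplex, and the combined rise
#' half-widths stay below half the A/B setpoint gap so that zero-jitter
#' step classification recovers the latent flags exactly.
#'
#' @param radius Length-2 interval for the phosphate radius (Angstrom).
#' @param twist_collective_halfwidth Half-width of the conformation-level
#'   twist shift (degrees).
#' @param twist_step_halfwidth Half-width of the independent per-step twist
#'   residual (degrees).
#' @param rise_collective_halfwidth Half-width of the conformation-level
#'   rise shift (Angstrom).
#' @param rise_step_halfwidth Half-width of the per-step rise residual
#'   (Angstrom).
#' @param p_aform Probability that a step is A-like.
#' @param jitter_scale Per-bead Gaussian jitter (Angstrom).
#' @return A list of ranges, class `ensemble_ranges`.
#' @export
ensemble_ranges <- function(radius = c(8.6, 10.2),
                            twist_collective_halfwidth = 2.0,
                            twist_step_halfwidth = 0.5,
                            rise_collective_halfwidth = 0.2,
                            rise_step_halfwidth = 0.05,
                            p_aform = 0.7,
                            jitter_scale = 0.1) {
  if (length(radius) != 2 || radius[1] > radius[2]) {
    abort("`radius` must be an interval c(min, max) with min <= max.")
  }
  if (radius[1] <= 0) abort("`radius` interval must be positive.")
  if (twist_collective_halfwidth < 0 || twist_step_halfwidth < 0 ||
      rise_collective_halfwidth < 0 || rise_step_halfwidth < 0) {
    abort("Half-widths must be non-negative.")
  }
  if (p_aform < 0 || p_aform > 1) abort("`p_aform` must be in [0, 1].")
  if (jitter_scale < 0) abort("`jitter_scale` must be non-negative.")
  structure(list(radius = as.numeric(radius),
                 twist_collective_halfwidth = twist_collective_halfwidth,
                 twist_step_halfwidth = twist_step_halfwidth,
                 rise_collective_halfwidth = rise_collective_halfwidth,
                 rise_step_halfwidth = rise_step_halfwidth,
                 p_aform = p_aform,
                 jitter_scale = jitter_scale),
            class = "ensemble_ranges")
}

#' Sample a synthetic duplex ensemble
#'
#' Draws `n` independent conformations: for each, a radius, eleven form
#' flags, and per-step twists and rises around the form-specific setpoints,
#' then builds the bead model with jitter. Reproducible under a fixed seed.
#'
#' @param n Number of conformations (>= 1).
#' @param ranges An [ensemble_ranges()] object.
#' @param seed Integer seed.
#' @param sequence Strand pair; see [build_duplex()].
#' @return A list of `duplex_model` objects with distinct conformation ids.
#' @export
#' @examples
#' ens <- sample_ensemble(3, seed = 1)
#' vapply(ens, function(m) m$conformation_id, "")
sample_ensemble <- function(n,
                            ranges = ensemble_ranges(),
                            seed = 1L,
                            sequence = waxs_sequence()) {
  if (n < 1) abort("`n` must be at least 1.")
  if (!inherits(ranges, "ensemble_ranges")) {
    abort("`ranges` must be an `ensemble_ranges` object.")
  }
  g <- .waxs_geom
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      form <- runif(11) < ranges$p_aform
      tw0 <- ifelse(form, g$twist_aform, g$twist_bform)
      rs0 <- ifelse(form, g$rise_aform, g$rise_bform)
      tw_shift <- runif(1, -ranges$twist_collective_halfwidth,
                        ranges$twist_collective_halfwidth)
      rs_shift <- runif(1, -ranges$rise_collective_halfwidth,
                        ranges$rise_collective_halfwidth)
      p <- helical_params(
        radius = runif(1, ranges$radius[1], ranges$radius[2]),
        step_twist = tw0 + tw_shift +
          runif(11, -ranges$twist_step_halfwidth, ranges$twist_step_halfwidth),
        step_rise = rs0 + rs_shift +
          runif(11, -ranges$rise_step_halfwidth, ranges$rise_step_halfwidth),
        step_form = form,
        jitter_scale = ranges$jitter_scale,
        conformation_id = sprintf("conf%05d", i)
      )
      build_duplex(p, sequence = sequence,
                   seed = sample.int(.Machine$integer.max, 1))
    })
  })
}

#' Ensemble manifest
#'
#' One row per conformation: id, latent radius, mean twist/rise, A-step
#' count and jitter scale, plus an optional model file path column.
#'
#' @param models List of `duplex_model`s.
#' @param paths Optional character vector of file paths, one per model.
#' @return A tibble.
#' @export
ensemble_manifest <- function(models, paths = NA_character_) {
  purrr::map2_dfr(models, rep_len(paths, length(models)), function(m, pth) {
    p <- m$latent_params
    tibble(conformation_id = m$conformation_id,
           radius = p$radius,
           mean_twist = mean(p$step_twist),
           mean_rise = mean(p$step_rise),
           n_aform_steps = sum(p$step_form),
           jitter_scale = p$jitter_scale,
           path = pth)
  })
}
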