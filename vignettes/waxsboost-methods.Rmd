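---
title: "Methods: learning helical structure from solution scattering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: learning helical structure from solution scattering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A solution small- and wide-angle X-ray scattering (SWAXS) measurement
reduces a molecular ensemble to a single one-dimensional curve, the
orientationally averaged intensity $I(q)$ over momentum transfer
$q = 4\pi\sin\theta/\lambda$. For a 12-base-paired RNA duplex the helical
geometry — radius, twist, rise, groove widths, how A-form-like the steps
are — is imprinted on this curve through the pair-distance distribution,
but extracting it by curve fitting requires explicit structural models.
`waxsboost` instead learns the inverse mapping: gradient-boosted tree
ensembles are trained on a large synthetic library of (profile, descriptor)
pairs and then applied to measured curves, with experimental errors
propagated by Monte-Carlo resampling of the profile.

The package covers the whole loop: a coarse-grained duplex generator, a
Debye-equation scattering calculator on a fixed q grid, a parametric
solution-condition model with additive-offset buffer-subtraction
correction, descriptor extraction from bead geometry, conformation-grouped
dataset assembly, model training and interrogation, and noisy inference.

## The duplex generator

Each conformation is built from a `helical_params` set: a phosphate radius,
eleven per-step twists and rises, eleven per-step form flags and a per-bead
jitter scale. Residues are reduced to three beads (phosphate, sugar, base)
placed on an ideal straight-axis helix; at the q range used here
(q ≤ 0.95 Å⁻¹, real-space resolution ≈ 2π/q ≈ 6.6 Å) bead-level
detail is sufficient, and the exact 72-bead pair sum stays trivially cheap.
Bead electron counts are the summed atomic numbers of the atoms assigned to
each bead (phosphate 47 e⁻ including both bridging oxygens; ribose 53 e⁻;
attached bases A 69, G 77, C 57, U 57 e⁻); the per-bead table is documented
in `R/helix-forge.R`.

A-like steps use fiber-model A-RNA setpoints (twist 32.7°, rise 2.81 Å)
with base pairs displaced 4.4 Å from the axis, so the axis runs through the
deep major groove. Non-A steps model the distorted geometry RNA duplexes
adopt away from the canonical A-form — reduced base displacement (0.8 Å)
with unwound, axially compacted step geometry (twist 30.0°, rise 2.25 Å).
Two choices here deserve comment:

* **Non-A setpoints are compact, not B-DNA fiber values.** B-DNA's rise
  (3.38 Å) would *lengthen* a 12-mer towards 37 Å, outside the 25–30 Å
  span of a 12-bp duplex, and RNA duplexes do not reach B-DNA geometry in
  solution; the experimentally relevant distortion (divalent-ion-induced)
  unwinds and *compresses* the helix while pulling base pairs toward the
  axis. With these setpoints, ensembles cover the 25–30 Å length span and
  reproduce the expected coupling of unwinding with major-groove
  shrinkage.
* **Collective-plus-residual sampling.** Helical fluctuations of duplex MD
  ensembles are dominated by collective modes (global unwinding or
  over-winding, stretching or compression). The sampler therefore draws,
  per conformation, a collective twist shift (±2.0°) and rise shift
  (±0.2 Å) applied to all steps, plus small independent per-step residuals
  (±0.5°, ±0.05 Å), rather than wide independent per-step values. Purely
  independent per-step draws would concentrate the ensemble variance in
  high-frequency structural detail that the orientationally averaged
  profile encodes only diffusely, which is neither how MD duplexes move
  nor a learnable target.

Per-bead Gaussian jitter (default 0.1 Å) adds residual local disorder on a
scale clearly below the collective variation. The phosphate radius is
uniform on 8.6–10.2 Å around the A-form 9.4 Å, and steps are A-like with
probability 0.7, reflecting a predominantly A-form RNA duplex with
substantial distorted content. The combined rise windows stay inside half
the A/non-A setpoint gap, so step classification recovers the latent flags
exactly on zero-jitter models.

The strand phase angle — the azimuthal offset between the two phosphate
backbones, which sets groove asymmetry — is a named parameter. Its default
(245.496°) is a calibration constant, fixed once so that the canonical
A-form duplex evaluates to a raw major groove width of 8.7 Å (see below).

## Descriptors

All five labels are computed from bead geometry, never copied from
generator latents (mirroring a pipeline in which structures are scored by
external analysis programs).

**Axis.** The helical axis is fitted in two stages: candidate directions
(principal axes of the phosphate cloud, the end-to-end base-pair vector,
and a coarse hemisphere scan) are ranked by a cylinder criterion — the
variance of phosphate-to-axis distances with the in-plane circle centre
solved in closed form — and the best candidate is refined by Nelder–Mead.
For zero-jitter models the phosphates lie exactly on a cylinder and the
construction axis is recovered to optimizer precision; round-trip tests
assert 1e-6 on radius, twist and rise. A one-turn helix is a degenerate
target for plain principal-component fitting (helical phase correlates
with height, tilting the leading axis), which is why the multi-candidate
start is needed.

**Radius** is the mean perpendicular phosphate-to-axis distance. **Twist**
is the mean signed angle between successive strand-1 phosphate azimuths
about the axis (beads carry no base plane, so this is a documented
simplification of base-pair-frame definitions); a left-handed result is an
error, not a value. **Rise** is the mean axial separation of base-pair
centers.

**Major groove width** is the minimal cross-strand phosphate–phosphate
distance on spline-interpolated backbone traces, scanned over the central
base pairs and restricted to the major-groove side, which is identified
from base orientation (base beads sit on the minor-groove bisector; a
cross-strand segment is major-groove when its midpoint azimuth opposes the
local base azimuth). The width is reported raw, without subtracting a
phosphate van der Waals diameter: groove widths of a few Ångström for
compacted duplexes would be negative under the subtracted convention, and
the canonical A-form calibration value of 8.7 Å is consistent with the raw
one. Note the direction of the twist–groove coupling in this geometry:
at *fixed* rise, unwinding lengthens the helical pitch and widens the
groove; the physically observed shrinkage of the major groove on unwinding
emerges when unwinding is coupled with axial compression, as in the
distorted (divalent-ion-like) step geometry. The monotonicity test
therefore follows the coupled unwinding–compression path.

**A-form class** counts A-like steps (0–11, giving the 12 discrete label
values for a 12-bp duplex). Steps are classified by nearest setpoint in
(rise, base displacement) coordinates, each standardized by half the
A/non-A gap — equivalently, thresholds midway between the setpoints.

## Scattering and solution conditions

Profiles are computed with the Debye equation on the default grid of 191
points, q = 0.000–0.950 Å⁻¹ at 0.005 Å⁻¹ spacing, with an exact pair sum
over all 72 beads and a Gaussian bead form factor
$f_i(q) = Z_i e^{-(q r_\mathrm{bead})^2/2}$ (default width 2.5 Å) to avoid
point-scatterer artifacts at the wide-angle end. The q = 0 limit is
handled analytically (sinc(0) = 1), so $I(0)$ equals the squared total
electron count.

Nine solution conditions (30, 50, 100, 200, 500 mM KCl; 0.25, 0.50, 1.00,
5.00 mM MgCl₂) replace explicit solvent/ion modelling with a parametric
map $I_\mathrm{cond}(q) = I(q)[1 + \epsilon g(q)] + b$, where
$g(q) = e^{-(q/0.2)^2}$ is a fixed low-q envelope and
$b$ is an additive background expressed as a fraction of $I(q_\mathrm{max})$.
Because the intensity spans about four decades over the grid, any
percent-level multiplicative modulation at low q would dwarf the high-q
scale on which the additive offset is defined; the amplitudes are
therefore calibrated so that condition-to-condition variation is carried
almost entirely by the additive term (offset fractions within ±3% of
$I(q_\mathrm{max})$, $\epsilon$ of order 10⁻⁶), keeping every fitted
offset below 10% of $I(q_\mathrm{max})$ — the documented bound for
buffer-subtraction corrections — while still giving each condition a
deterministic, distinguishable signature.

The buffer-subtraction offset between a theoretical curve and a measured
one minimizes $\sum_j [I(q_j) + c - I_\mathrm{exp}(q_j)]^2/\sigma'(q_j)^2$,
i.e. the $\sigma'$-weighted mean residual in closed form. The error
propagation rule producing $\sigma'$ is pluggable (default: identity);
only the fit's weights depend on it, never its closed form.

## Dataset and models

Features are base-10 logarithms of the condition-modulated intensities
(the base is immaterial to tree models and documented for
reproducibility); labels are computed once per conformation and replicated
across its nine condition rows. Splitting shuffles *conformations*
(68/17/15 train/validation/test, floor rounding with the remainder to
training) so that all nine profiles of a conformation share one tag, and a
hash of the test rows is frozen at split time and re-checked before every
final evaluation.

Boosted ensembles use squared-error (regression) or softmax
cross-entropy (12-class) objectives with centralized defaults: learning
rate 0.1, depth 6, L2 penalty 1, L1 0, early stopping after 50 stagnant
rounds, 750 trees in cross-validation and up to 7500 in final training.
The classifier's early stopping tracks classification error rather than
log-loss, since the reported quantity is accuracy. Cross-validation folds
partition conformations, consistent with the split principle. Five
variants are trained per descriptor: noise-free, noisy (5% multiplicative
Gaussian noise on training intensities, S/N = 20, with negative draws
redrawn from the positive-truncated law), sparsely (100 q points) and
densely (400) resampled, and a random-label control drawn uniformly over
each label's observed domain. Linear baselines (least squares via pivoted
QR, closed-form ridge, LASSO via `glmnet`) run under identical splits.
Feature importances (gain and weight) are mapped back to q by column
index and normalized to sum to one.

## Noisy inference

Each point of a measured profile with errors $\sigma(q)$ is treated as an
independent normal draw centred on the measurement with standard deviation
$\alpha\sigma(q)$; presets low/medium/high correspond to
$\alpha$ = 0.2, 1.0, 2.0. Draws at or below zero — frequent at high q for
large $\alpha$ — are replaced by draws from the positive-truncated normal,
because the log feature is undefined otherwise and discarding curves would
bias the high-q statistics; this choice (truncation versus discarding) is
a documented convention of this implementation. 5000 profiles are sampled
by default, with a warning below 1000. Prediction distributions are
summarized by a Freedman–Diaconis histogram (fallback 50 bins), with the
mode (maximal-count bin centre, ties toward the smaller value) preferred
over the mean for noisy data; "mode recovery" is judged against the
model's own test RMSE, since the residual bias of a trained model — not
the sampling noise — sets the scale on which a mode can recapitulate the
truth.

## Problem sizes and numerical choices

The package's own validation experiments use a 2000-conformation ensemble
(18 000 profiles) for the recovery and control experiments, with the
monotone-direction studies (training-set size, q-resolution, noise level)
run on a 600-conformation ensemble at reduced tree counts; the pipeline
smoke configuration uses tens of conformations. These sizes are the package's choices for routine
validation on a single CPU; the generator scales to the
5000-conformation, 45 000-profile regime the method targets by changing
one configuration number.

Other numerical conventions: the q grid requires exact divisibility of its
range (no silent truncation); grid mismatches anywhere (offset fit,
prediction) are hard errors rather than implicit resampling; groove-scan
failures raise errors rather than returning zero; the dense groove scan
uses 300 spline samples per strand (discretization error ≈ 5 × 10⁻⁵ Å at
the canonical geometry); and every stochastic step (jitter, ensemble
sampling, splitting, noise, training) is seeded explicitly.

## What the synthetic generator does and does not emulate

The generator reproduces the *structure* of the learning problem: smooth
profiles on the documented grid, condition-replicated curves that must be
kept together when splitting, descriptor labels computed by an external
geometric analysis, and class labels with exactly twelve values. It does
not emulate solvent and ion scattering (beyond the parametric condition
model), sequence-dependent base-pair geometry, bending or fraying, or
absolute experimental calibration. Passing recovery tests therefore shows
that the pipeline can invert its own forward model at realistic noise
levels — the precondition for the method — not that a model trained on
these synthetic curves transfers to beamline data; for real applications
the training library should come from solvated all-atom structures, as in
the MD-based workflow this package emulates at desk scale.

## Known limitations

* The coarse-grained duplex has flat base pairs (no inclination or
  propeller), a single straight axis, and no sequence-dependent geometry;
  descriptors derived from it are internally consistent but not
  interchangeable with all-atom analysis outputs.
* The twist definition via phosphate azimuths differs from
  base-pair-frame definitions by a constant-ish offset on distorted
  geometries.
* The condition model is a two-parameter caricature of ion-dependent
  scattering; it produces the documented statistical footprint (nine
  distinguishable conditions, offsets within the 10% bound) and nothing
  more.
* Groove width is a minimum over a scanned window and is therefore the
  descriptor most sensitive to local geometry; its recovery is
  correspondingly the hardest among the five.
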