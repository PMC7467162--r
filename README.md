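# waxsboost

Helical structure descriptors of RNA duplexes from solution X-ray
scattering, by gradient-boosted trees.

## The problem

Solution small- and wide-angle X-ray scattering (SWAXS) collapses the
conformational state of a molecule into one curve, the orientationally
averaged intensity *I(q)* over momentum transfer *q* = 4π sin θ / λ. For a
12-base-paired RNA duplex, the helical geometry — radius, twist, rise,
major groove width, and how A-form-like the base-pair steps are — shapes
this curve through the pair-distance distribution, but reading the
geometry back out normally requires explicit structural modelling.

`waxsboost` learns the inverse map instead. It generates a large synthetic
library of coarse-grained duplex conformations, computes their SWAXS
profiles with the Debye equation,

> *I(q)* = Σᵢ Σⱼ *fᵢ(q) fⱼ(q)* sin(*q dᵢⱼ*)/(*q dᵢⱼ*),

labels every profile with five structural descriptors extracted from the
bead geometry, and trains one gradient-boosted tree ensemble per
descriptor (a 12-class softmax model for the discrete A-form fraction
*k*/11, squared-error regressors for the rest) on the base-10 logarithms
of the intensities at 191 q points (0.000–0.950 Å⁻¹, 0.005 Å⁻¹ spacing).
Trained models are then applied to measured profiles with experimental
errors propagated by Monte-Carlo resampling: every q point is redrawn from
a normal law of width α·σ(q) (α = 0.2 / 1.0 / 2.0 presets), and the
prediction *distribution* — in particular its mode — is reported rather
than a point estimate. Feature importances (gain and weight) are mapped
back onto the q axis to show which scattering angles carry which
structural information.

It is intended for structural-bioinformatics users who want a
self-contained, desk-scale re-implementation of the
scattering-to-structure learning loop: dataset construction, splitting
that keeps the nine salt-condition profiles of each conformation together
(30–500 mM KCl, 0.25–5 mM MgCl₂), buffer-subtraction offset fitting,
model training with the five standard variants (noise-free, noisy, sparse,
dense, random-label control), cross-validation, linear baselines, and
noisy inference.

## Worked example

```r
library(waxsboost)

# 1. forge a small ensemble and assemble the labeled dataset
ens <- sample_ensemble(400, seed = 3)
ds  <- assemble_dataset(ens)                 # 400 x 9 = 3600 profiles
ds  <- split_by_conformation(ds, seed = 5)   # 68/17/15 by conformation

# 2. train the helical-radius regressor
cfg <- training_config(n_trees_final = 600, early_stopping_patience = 50,
                       seed = 7)
m <- train_descriptor_model(ds, "radius", cfg)
m
#> <waxs_model> radius (regression), 191 q features
#>   MSE train 2.934e-06 | validation 0.01884 | test 0.02832 | test R2 0.874

# 3. push a noisy test profile through the model
i    <- which(ds$split == "test")[1]
I    <- unname(10^ds$features[i, ])
prof <- swaxs_profile(ds$qgrid, I, sigma = 0.02 * I)
smp <- sample_noisy_profiles(prof, "low", n = 2000, seed = 11)
predict_distribution(m, smp)
#> <waxs_prediction> radius at alpha = 0.2: mode 9.666, mean 9.646, sd 0.02884 (n = 2000)
ds$labels$radius[i]
#> [1] 9.486587
```

The printed numbers mean: the regressor explains 87% of the held-out
radius variance on this small library (`test R2 0.874`); pushing one
noise-free test profile through Gaussian resampling at the low error
level gives a tight prediction distribution (sd 0.03 Å) whose mode,
9.67 Å, recapitulates the true 9.49 Å radius at the model's own accuracy
scale (test RMSE ≈ 0.17 Å here). Larger libraries tighten all of this;
`run_pipeline()` drives the full forge → score → scatter → dataset →
train loop from one configuration, and `autoplot()` methods display
profiles, importance traces and prediction histograms.

A command-line front end with the same verbs is installed with the
package:

```sh
Rscript inst/cli/waxsboost forge --n 100 --seed 1 --out runs/ens --pdb
Rscript inst/cli/waxsboost score --pdb runs/ens/conf00001.pdb --out scores.csv
```

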