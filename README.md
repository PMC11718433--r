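# pelletox

Oxygen supply analysis and reaction–diffusion modelling for pellets of
filamentous fungi.

Submerged cultures of *Aspergillus niger* and related fungi grow as dense,
near-spherical **pellets**. Oxygen diffuses in from the broth through the
hyphal network and is consumed by the biomass, so only an outer shell is
oxygen-supplied while the pellet centre can be anoxic. `pelletox` is for
bioprocess researchers who combine 3D (µCT-type) pellet images with
microelectrode oxygen depth profiles and want to quantify that supply and
model it mechanistically.

## What it computes

* **Shell morphometry** — hyphal volume fraction `ch(r)` in a 50 µm
  central sphere plus concentric 15 µm shells (Otsu binarisation, voxel
  counting), sphericity (volume-equivalent sphere area over convex-hull
  area), axis ratio, and 2D descriptors including the morphology number
  `MN = 2·sqrt(area·solidity/π) / (Feret·aspect ratio)`.
* **Profile processing** — replicate averaging, border detection (95% of
  the maximum concentration; hyphal fraction cutoff 0.005 on the image
  side), alignment of both data sources on a common radius, oxygen
  penetration depth and active part percentage (APP).
* **Steady-state oxygen simulation** — the 1D spherical model

  dc/dt = (1/r²) d/dr ( D_eff r² dc/dr ) − q(c),
  D_eff = D_bulk (1 − ch)^a,
  q = (ρ_h/Y_X/O2) · c/(K_XO + c) · µ_max · ch  (+ optional maintenance term),

  discretised with a conservative second-order finite-volume scheme on
  100 nodes and solved both transiently (stiff method of lines) and by
  Newton iteration.
* **Per-pellet parameter estimation** — bounded Levenberg–Marquardt least
  squares with 50 multistart points and complex-step steady-state
  sensitivities; model variants ranked by small-sample AICc; cohort
  summaries with the spherical-pellet filter and one-way ANOVA.
* **Synthetic data** — seeded voxel phantoms and forward-model oxygen
  profiles (`synth_preset()`), so the full pipeline runs and is tested
  without any measured data.

## Worked example

```r
library(pelletox)

pr      <- synth_preset("hyperbranching", seed = 1)
shells  <- gen_radial_hyphal_fraction(pr$spec)
profile <- gen_oxygen_profile(shells, pr$params, pr$spec)

rec <- run_pellet(shells, profile, pr$params,
                  pellet_id = "H-17.1", strain = "H",
                  border_depth = attr(profile, "truth")$border_depth)
rec
#> Pellet H-17.1 (strain H, spherical)
#> Supply: penetration 188 um, APP 92.4%, max dO2/dr 0.0714 mg/L/um
#> Fit (growth_only; free: y_xo2)
#>   y_xo2     2.772
#>   RSS 0.0009473, MAE 0.002409 mg/L, AICc -386.84 (n = 37, best start 34/50)
```

Reading this: the simulated hyperbranching pellet (365 µm border radius)
is oxygen-supplied over its outer 188 µm, which holds 92% of its hyphal
volume; fitting the oxygen-related biomass yield to the noisy synthetic
profile recovers the generating literature value (2.77 kg biomass per kg
O₂) with a residual MAE of 0.0024 mg/L, well inside the injected sensor
noise (0.03 mg/L at the plateau, signal-proportional inside the pellet).

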