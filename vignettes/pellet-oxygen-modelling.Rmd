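---
title: "Modelling oxygen supply in filamentous fungal pellets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oxygen supply in filamentous fungal pellets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelletox)
```

## The problem

Submerged cultures of filamentous fungi such as *Aspergillus niger* grow as
dense, near-spherical pellets. Oxygen is usually the limiting substrate:
it diffuses in from the culture broth through the hyphal network and is
consumed by the growing biomass, so only an outer shell of the pellet is
oxygen-supplied while the centre can be anoxic. How deep that supplied
layer reaches depends on the pellet's local hyphal volume fraction
`ch(r)` — denser networks hinder diffusion and consume more — and on the
consumption kinetics of the strain.

`pelletox` implements the complete analysis chain for this problem:

1. **Shell morphometry** (`shell_hyphal_fraction()`): from a binarised 3D
   pellet image, the hyphal volume fraction is counted in a 50 µm central
   sphere and concentric 15 µm shells around the foreground mass centre,
   together with whole-pellet shape metrics (sphericity from the convex
   hull, axis ratio from the second-moment tensor) and 2D descriptors
   including the morphology number.
2. **Oxygen profile processing** (`align_profiles()` and friends):
   replicate microelectrode depth profiles (10 µm steps) are averaged and
   aligned with the image data on a common radial coordinate, using the
   pellet border as the shared fixed point; penetration depth and the
   active part percentage (APP) follow.
3. **Reaction–diffusion modelling** (`steady_state_profile()`): the
   steady-state oxygen field is simulated from `ch(r)` with a 1D spherical
   diffusion–consumption model.
4. **Parameter estimation** (`fit_parameters()`, `select_model()`):
   per-pellet kinetic parameters — typically the oxygen-related biomass
   yield — are estimated by multistart bounded least squares, with AICc
   deciding between consumption-model variants.
5. **Synthetic data** (`synth_spec()`, `gen_pellet_image()`,
   `gen_oxygen_profile()`): seeded phantoms and forward-model profiles so
   that every stage above is testable without measured data.

## The model

Oxygen transport and consumption in a spherically symmetric pellet:

$$\frac{\partial c}{\partial t} = \frac{1}{r^2}\frac{\partial}{\partial r}
\left( D_\mathrm{eff}(r)\, r^2 \frac{\partial c}{\partial r} \right) - q(c, r),$$

with hindered effective diffusivity

$$D_\mathrm{eff} = D_\mathrm{bulk} \,(1 - c_h)^a,$$

and Monod consumption for growth,

$$q = \frac{\rho_h}{Y_{X/O_2}} \frac{c}{K_{XO} + c}\, \mu_\mathrm{max}\, c_h,$$

optionally extended by maintenance metabolism,

$$q = \frac{\rho_h}{Y_{X/O_2}} \frac{\max(c - c_\mathrm{crit}, 0)}{K_{XO} + c}
\mu_\mathrm{max} c_h + m_{O_2,\mathrm{max}}\, \rho_h \frac{c}{K_{MO} + c} c_h.$$

The growth term of the maintenance variant is floored at zero below the
critical concentration; written without the floor it would produce
negative consumption (oxygen production) for `c < c_crit`, which is
unphysical.

Boundary conditions are zero flux at the centre (symmetry) and a Dirichlet
value at the pellet border fixed at the maximum measured concentration of
that pellet. Growth is hours-slow compared to transport and consumption
(`characteristic_times()`), so `ch(r)` is held constant while the oxygen
field equilibrates (pseudo-steady state).

### Default parameters

`kinetic_params()` ships literature values for *A. niger* at 37 °C:
`d_bulk` = 8.7e-6 m²/h, hindrance exponent `a` = 1.76, hyphal dry-weight
density `rho_h` = 150 kg/m³, yield `y_xo2` = 2.77 kg/kg, `k_xo` = 2.5e-5
kg/m³, `k_mo` = 1.5e-5 kg/m³, `c_crit` = 1e-5 kg/m³, `m_o2_max` = 7.2e-3
kg/kg/h, and `mu_max` = 0.16 h⁻¹ (regular strain) or 0.24 h⁻¹
(hyperbranching strain; `strain_params()`). Note that `rho_h` is a
dry-weight density applied to a wet-volume fraction; we use the literature
value as printed. Concentrations cross the user interface in mg/L
(1 mg/L = 1e-3 kg/m³); the solver works in kg/m³, m, h.

## Numerics

The spatial direction is discretised on 100 equidistant nodes with a
conservative second-order finite-volume scheme: diffusive fluxes are
evaluated at cell faces with the face-averaged hyphal fraction, the
centre node uses the symmetry limit of the spherical Laplacian, and the
border node is held at the Dirichlet value. We deliberately use a flux-form
scheme rather than an upwind-biased stencil: pure diffusion has no
transport direction to upwind, and the scheme is certified against the
closed-form first-order-kinetics sphere solution
(`c(r) = c_s (R/r) sinh(φ r/R)/sinh(φ)`), with max relative error < 1% at
100 nodes and < 0.25% at 200 nodes.

Two solvers expose the steady state:

* `steady_state_profile()` integrates the transient from a uniform initial
  condition at the surface concentration with a stiff (lsoda) method-of-lines
  integrator and records the first simulated time at which the maximum
  relative concentration change drops below 1e-6 per millisecond
  (`time_to_steady`). Integration continues until the drift is three
  decades smaller, so the returned profile is fully settled.
* `steady_state_newton()` solves the discretised steady system directly by
  pseudo-transient continuation ending in Newton iteration with a
  tridiagonal Jacobian. It is orders of magnitude faster and is the path
  used inside the fitting loops; the two solvers agree to better than
  1e-4 relative and this agreement is asserted in the test suite.

### How long does "steady" take?

With the literature kinetics the initial condition (pellet saturated at
the surface concentration) relaxes by draining the interior at the nearly
zero-order volumetric rate `q_max ≈ ρ_h µ_max c_h / Y`, which for a 500 µm
pellet at `c_h = 0.1` takes about `c_s/q_max ≈ 28 s` of simulated time,
followed by a short exponential tail — the criterion above is typically
reached after tens of seconds of simulated time (the `time_to_steady`
value reported by the solver and by `scripts/acceptance.R`). The steady
profile itself is of course independent of how long the transient takes;
`steady_state_profile()` therefore integrates as long as needed (cap
300 s) rather than stopping at a fixed horizon. Note that one millisecond
of *model time* in the solver's native hour units (1e-3 h) is 3.6 s, so
descriptions of this transient as "milliseconds" depend entirely on which
unit the integrator counts in; in SI seconds the relaxation is tens of
seconds.

## Data processing conventions

* **Borders.** The image-side border is where the shell-wise hyphal
  fraction falls to 0.005 (not exactly 0, so a single protruding hypha
  does not drag the border out), linearly interpolated between bins. The
  profile-side border is where the mean profile reaches 95% of its
  maximum, scanning from the deep end outward; scanning outward avoids
  boundary-layer dips outside the pellet. The two borders are the shared
  fixed point of the alignment. The maximum concentration `c_max`, which
  also anchors the simulation's Dirichlet boundary value, is estimated as
  the mean of the approach-region samples outside the border rather than
  the sample maximum: the maximum of a noisy series is an upward-biased
  order statistic, and anchoring the boundary condition on it leaves a
  systematic residual in the profile tail that distorts AICc model
  comparison; the plateau mean estimates the same quantity unbiasedly and
  coincides with the maximum for noiseless data.
* **Interpolation of `ch`.** Shell values are anchored at bin mid-radii
  and interpolated linearly, flat below the innermost anchor and (for the
  simulation grid) beyond the outermost; values are clamped to
  \[0, 0.999\] so the effective diffusivity stays positive.
* **Penetration depth.** "Oxygen above zero" uses a threshold of
  0.05 mg/L (≈1% of air saturation) because a noisy sensor never reads
  exactly zero; the threshold is a parameter and is reported with the
  output.
* **Gradients.** Second-order central differences on the mean profile
  without smoothing; endpoints excluded.
* **Cohort rule.** Only pellets with axis ratio ≥ 0.7 *and* sphericity
  ≥ 0.95 enter cohort means.

## Parameter estimation

Per pellet, the residuals are the differences between measured and
simulated concentrations at the aligned measurement radii (in mg/L, so
the mean absolute error is on the measurement scale). Estimation uses
bounded Levenberg–Marquardt least squares from 50 multistart points
sampled log-uniformly within bounds that bracket the literature values by
at least an order of magnitude (linear-uniform for `c_crit`, whose lower
bound is 0). Gradients are computed by complex-step differentiation
propagated through the steady state: the kinetics are differentiated with
an imaginary step (no subtractive cancellation) and one tridiagonal
sensitivity solve per parameter turns this into the exact derivative of
the implicitly defined steady state. The maintenance variant contains a
kink (`max(c - c_crit, 0)`), which breaks analyticity, so it falls back
to central finite differences; the mode used is recorded in the result.

Model variants and free-parameter sets are compared with the
small-sample-corrected Akaike criterion
`AICc = n ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)` with `k` = number of fitted
parameters + 1 (the residual variance). Ties are broken toward fewer
parameters. The shipped candidate list (`default_fit_candidates()`)
spans the single-yield growth-only fit to the full five-parameter
maintenance kinetics and is configurable.

## The synthetic-data generator

Because measured µCT volumes and microprofiles are not redistributable,
the package generates its own test universe:

* **Radial profiles**: a logistic core-to-rim transition (two parameters,
  matching the qualitative shapes of measured profiles) with a terminal
  sub-cutoff bin so the border rule recovers the pellet radius within one
  shell width.
* **Phantoms**: each voxel is foreground with probability equal to the
  target fraction of its shell, so shell counting recovers the target up
  to binomial error; ellipsoids scale the axes anisotropically. Synthetic
  voxels default to 2 µm (measured data are 1 µm) to keep phantoms
  desk-scale; the voxel size is a stored field.
* **Profiles**: the forward model sampled every 10 µm from the border
  inward, a 100 µm outside-pellet plateau at the surface concentration
  (the approach region of a real measurement), and Gaussian sensor noise
  truncated at zero. The noise is *signal-proportional* (sd = `noise_sd`
  at the surface concentration, scaling with the local value): the
  current of an amperometric sensor is proportional to the oxygen
  partial pressure and its zero reading is the stable calibration point.
  This matters beyond realism — noise that is additive *and* truncated at
  zero would put a positive bias of 0.4 sd on every anoxic-core sample,
  which perfectly mimics the small positive core plateau of the
  maintenance-kinetics variant and would systematically flip AICc model
  selection toward maintenance metabolism regardless of the noise level.
  The default noise (0.03 mg/L at saturation) is in the precision class
  of Clark-type microsensors and below the 0.05 mg/L anoxia threshold,
  so zero readings remain identifiable.
* **Presets** (`synth_preset()`): a "regular" morphotype (450 µm radius,
  denser core) and a "hyperbranching" one (350 µm, denser rim, higher
  µ_max). The presets were chosen once so that the simulated supplied
  layer is 150–250 µm thick with an anoxic centre — the qualitative
  regime of measured pellets; they are emulations, not digitised
  measurements.

What passing synthetic tests do **not** show: real µCT noise,
reconstruction artefacts, non-spherical pellet shapes beyond ellipsoids,
electrode suction artefacts near the pellet centre, or an external
mass-transfer boundary layer (the plateau is flat by construction).
Because the measured 95%-of-maximum border convention places the detected
border slightly inside the simulated Dirichlet boundary (simulated
profiles reach their maximum exactly at the border, measured ones in the
bulk), recovery tests align synthetic profiles with the generator's known
border; with detected borders a small inward bias of order 10 µm enters.

A note on scale: the presets are capped at desk-scale phantom sizes, so
their supplied layer is a larger volume fraction of the pellet (APP
80–95%) than in the larger measured pellets, where the same ~200 µm
supplied depth on a ~1 mm pellet yields APP around 50%. The APP
computation itself is exact sphere-shell geometry and is verified against
the closed form `100·(1 − ((R−d)/R)³)`.

## A worked example

```{r example, eval = FALSE}
pr <- synth_preset("hyperbranching", seed = 1)
shells <- gen_radial_hyphal_fraction(pr$spec)
profile <- gen_oxygen_profile(shells, pr$params, pr$spec)

rec <- run_pellet(shells, profile, pr$params,
                  pellet_id = "H-17.1", strain = "H",
                  border_depth = attr(profile, "truth")$border_depth)
rec
```

## Design choices and limitations

* Voxels are assigned to shells by their centre distance to the
  foreground centroid (no partial-volume weighting); bins truncated by the
  image edge are normalised by their in-image volume.
* The convex hull for sphericity is computed over support points of the
  foreground voxel corners in 1500 quasi-uniform directions; this inner
  approximation is exact for the sampled directions and its area error is
  well below the 0.02 classification tolerance.
* `Eq.`-level choices that the data cannot distinguish (e.g. the exact
  candidate list for model selection, or the border-scan direction) are
  parameters, not constants.
* The model is strictly 1D-spherical: convection, multi-substrate
  coupling and full-3D geometry are out of scope. Nonspherical pellets
  are flagged and excluded from cohort means rather than modelled.
* Problem sizes used in the shipped tests (phantoms ≤ 250 µm radius at
  2 µm voxels, 100-node grids, 6–50 multistart points, 20-pellet
  recovery studies) were chosen as the smallest sizes at which the
  statistical assertions are stable.
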