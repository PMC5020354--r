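---
title: "Dipole orientation and organization forms from polarized FLIM of single GUVs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dipole orientation and organization forms from polarized FLIM of single GUVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(guvflim)
```

## The measurement

A giant unilamellar vesicle (GUV) imaged confocally through its equator
appears as a bright ring: the membrane seen edge-on. When the excitation
laser is linearly polarized (along the image axis we call Y; the vertical
image axis is Z; X is the optical axis) and the fluorophores are embedded in
the bilayer with a fixed mean angle ν between their absorption transition
dipole and the local membrane normal, photoselection makes the ring
anisotropic: membrane fragments whose normal is parallel to the polarization
(left/right of the ring, the "Y sectors") and fragments whose normal is
perpendicular to it (top/bottom, the "Z sectors") absorb differently.

With the membrane azimuth integrated out (the bilayer is rotationally
symmetric about its normal), the relative absorption of the two sector
families has the closed form

- `A_Y(ν) = cos²ν` — normal parallel to the polarization,
- `A_Z(ν) = (1 − cos²ν)/2` — normal perpendicular to it, the factor 1/2
  being the azimuth average of sin²φ,

so that `A_Y + 2 A_Z = 1` for every ν, and the general ring position ψ
(measured from the Y axis) interpolates between them:
`w(ν, ψ) = cos²ν cos²ψ + sin²ν sin²ψ / 2`. At `cos²ν = 1/3` — the magic
angle, 54.74° — the ring is exactly uniform, which is also why an
orientationally disordered sample is indistinguishable from one at the magic
angle.

Measured fluorescence is absorption times quantum yield, and the yield of a
multi-exponential emitter is proportional to its amplitude-averaged lifetime
`<τ> = Σaᵢτᵢ / Σaᵢ`. The pooled sector fluorescence ratio therefore obeys

```
R = F_Z / F_Y = (<τ>_Z / <τ>_Y) · (1 − cos²ν) / (2 cos²ν)
```

which inverts in closed form: with `T = <τ>_Z / <τ>_Y`,

```
cos²ν = T / (2R + T),   ν = arccos √(cos²ν).
```

This lifetime weighting is not cosmetic. If spectroscopically distinct
species orient differently — say a short-lived form standing vertical and a
long-lived form lying in-plane — the raw intensity ratio is biased by their
yield difference; the package's test suite constructs exactly that scenario
and shows the unweighted inversion is off by tens of degrees while the
weighted one recovers the absorption-weighted mean `⟨cos²ν⟩` (which is what
the method estimates for any mixture).

```{r closed-form}
invert_orientation(ratio_R = 1, tau_Z_ns = 1, tau_Y_ns = 1)
```

## Detection model and the emission-side assumption

Emission is collected along X and split by analyzers into a parallel (Y) and
a perpendicular (Z) channel; the instrumental G factor (default 1.044, the
reference setup's example value) corrects their unequal efficiency. Total
intensity is estimated as `F = F∥ + 2G·F⊥` and anisotropy as
`r = (F∥ − G·F⊥)/(F∥ + 2G·F⊥)`.

The `F∥ + 2G F⊥` estimator is exact only if the two emission components
orthogonal to Y are equal on average ("transverse-isotropic detection").
For an immobile cone distribution this holds exactly at the Y sectors and
approximately elsewhere; the package adopts it consistently on both the
analysis side and the simulator side, i.e. `polarized_emission_fractions()`
assigns the perpendicular channel the mean of the two transverse emission
components. This is the unique choice under which the total-intensity
estimator, the sector ratio law above, and the classic photoselection limits
(r = 1 for a single dipole along Y, r = 0.4 for an isotropic immobile
ensemble, r = (3cos²β − 1)/5 for an emission dipole on a β-cone) are all
satisfied simultaneously; a literal single-direction perpendicular projector
would break total-intensity conservation at the Z sectors and bias the
recovered ν by several degrees. Out-of-plane detection geometry and high-NA
depolarization are out of scope.

The absorption-emission dipole angle β is assumed 0 in the inversion (for
the compounds of interest the fundamental anisotropy r₀ ≈ 0.4 implies β of a
few degrees); `beta_from_fundamental_anisotropy()` quantifies this and the
simulator accepts β > 0 for realism checks.

## Decay analysis

TCSPC histograms are fit by Poisson maximum likelihood with the model
`I(t) = Σ aᵢ exp(−t/τᵢ) + bg` integrated over each bin — not by unweighted
least squares, because sub-percent amplitude components are far below the
Gaussian noise floor of the bright early bins. Two fitting modes:

- `fit_decay_free()`: lifetimes and amplitudes free (log-parameterized BFGS,
  5 starts: a deterministic geometric lifetime grid plus seeded jitter; ties
  broken by likelihood). Components are reported sorted by lifetime and can
  be mapped onto the library with `match_components_to_library()`
  (0.1 ns matching tolerance).
- `fit_decay_fixed()`: lifetimes pinned to the organization-form library of
  amphotericin B — tetramer 0.35 ns, parallel dimer 1.8 ns, monomer 3.0 ns,
  antiparallel dimer 6.8 ns — with only non-negative amplitudes and a flat
  background free. This likelihood is convex; it is solved by Fisher-scoring
  IRLS in which every step is a weighted non-negative least-squares problem,
  which is immune to the flat boundary asymptote that stalls log-scale
  quasi-Newton when a component's amplitude approaches zero. The monomer is
  excluded by default (organization-form tables for membrane-bound AmB carry
  no monomer row) but selectable via `subset`.

Fractions are amplitude fractions (`100·aᵢ/Σaᵢ`), summing to 100; intensity
weighting can be derived from the returned components if needed. Goodness of
fit is the reduced Pearson chi-square; fraction standard errors come from
the observed information. Tail fitting starts at the histogram peak
(`fit_start_policy = "peak"`); there is no IRF deconvolution, so a simulated
IRF must stay small against the 0.35 ns component or be disabled.

Time-resolved anisotropy `r(t) = r₀ exp(−t/θ)` is fit by weighted least
squares on the per-bin anisotropy, with weights from Poisson error
propagation. θ is the only nonlinear parameter, so it is profiled on a log
grid and polished with Brent's method; a fit hitting 100× the observation
window is flagged `theta_unbounded` (immobile limit).

## Image pipeline

`detect_vesicle()` thresholds bright pixels at background + 5 robust σ, fits
an intensity-weighted algebraic (Kasa) circle — which stays unbiased for
partially clipped rings, so border-touching vesicles fail the geometry check
loudly instead of being mis-fit — requires the bright pixels to actually lie
on the fitted circle, and refines the radius on the azimuthally averaged
radial profile. `build_sector_masks()` intersects the annulus
(radius ± half-width, default 3 px ≈ 2 lateral PSF radii) with ±aperture/2
cones about the four half-axes; the default aperture is 20° (read as the full
cone, axis ± 10°; the alternative per-side reading is available by passing
40°). Background is the median total fluorescence outside 1.5 ring radii — a
declared default, not an inferred one. Symmetric sectors are pooled before
any fit, per-sector `<τ>` comes from the pooled photon histogram (free
single-exponential by default; library-constrained or multi-component for
mixtures), and `estimate_orientation()` composes the whole chain, propagating
a first-order Poisson uncertainty from the sector totals into σ_ν (per-image;
a spread over repeated vesicles is the more honest error in practice).

Aperture sensitivity is quantified by `cone_aperture_scan()`: the estimate
varies only slightly with the integration cone (wider cones average more ring
curvature, pulling ν toward the magic angle by a fraction of a degree at
20°-40°).

## The simulator and what passing tests do (and do not) show

`simulate_guv_stack()` is a photon-level forward model: a sharp ring
deposited by bilinear splatting, weighted per arc point by the excitation
law and split between channels by the emission fractions, scaled per
population by its quantum yield (`∝ <τ>`), blurred by a Gaussian PSF
(σ 0.14 µm, matching a 140 nm lateral beam radius), thinned by 1/G in the
perpendicular channel, and read out as independent per-pixel, per-time-bin
Poisson counts with a uniform-in-time background. Defaults are the reference
study conditions: 17 µm vesicle, 0.1 µm pixels, G 1.044, 20° aperture,
background 0.5 counts/pixel/channel, 10⁶ expected photons pooled over the two
Y sectors (the paper-level budget; the generator normalizes its photon budget
on the Y sector pair at the configured aperture). The decay cube defaults to
128 bins × 0.2 ns — coarse enough to keep a 260×260×128 double-channel cube
in memory, fine enough for the 1-2 component sector fits; standalone decay
histograms default to the classic 4096 bins × 25 ns. Everything is
bit-reproducible under the mandatory seed.

What the simulator does **not** emulate: out-of-plane membrane signal
surviving the confocal section (the focal depth enters only through the
stated 1.468 µm confinement), 3-D PSF structure, photobleaching and blinking,
membrane undulations, rotational diffusion during the excited state, and
detector afterpulsing. Parameter-recovery results on synthetic stacks
therefore validate the estimator chain — segmentation, pooling, Poisson
fitting, inversion — under the model's own noise, not instrument systematics.

A statistical note frozen into the test expectations: the tetramer amplitude
fraction of the sterol-free composition (0.2%) sits at the information limit
of a 10⁶-photon decay — its Fisher standard error is ≈0.4 points, four times
the reported spread — so its 20-replicate median is intrinsically unstable
even though the optimizer provably reaches the global maximum-likelihood
solution; the corresponding acceptance expectation documents this rather than
hiding it. All other fractions, and the dominant component of every
composition, recover comfortably.

The confocal volume helper uses the Gaussian effective volume
`V = π^{3/2} y₀² x₀` (0.080 fL at y₀ = 140 nm, x₀ = 734 nm); the naive
ellipsoid `4/3·π y₀² x₀` (0.060 fL) is provided for comparison but the
Gaussian form is the default because it reproduces the reference value.

## Numerical choices

- Angles cross module boundaries in degrees and are converted to radians
  internally; ν is reported in [0°, 90°] (cone symmetry makes ν and 180°−ν
  indistinguishable). `cos²ν` is computed with `cospi` so ν = 90° is exactly
  degenerate and rejected by the forward ratio.
- Azimuth averages in `polarized_emission_fractions()` use a 64-point
  periodic midpoint rule; the integrands are trigonometric polynomials of
  degree ≤ 4, for which that rule is exact, far inside the 1e−6 contract.
  The simulator uses the equivalent closed forms
  (`⟨μ_y⁴⟩ = A⁴ + 3A²B² + 3/8·B⁴`), cross-checked against the quadrature in
  the tests.
- IRLS for the library fit stops at a 1e−12 relative step or a satisfied KKT
  score; the free fit uses `reltol = 1e−12` BFGS with analytic bin-integral
  gradients implicit in the likelihood.
- Degenerate inputs error early and specifically: empty histograms, fewer
  photons than parameters, ν = 90° forward ratio, non-positive sector
  ratios, mismatched channel binning, rings touching the border, blank
  fields.

## Workflow entry points

`cmd_simulate()`, `cmd_analyze()`, `cmd_fit_decay()` and
`cmd_scan_aperture()` run the full workflow from schema-validated YAML/JSON
configs (unknown keys are rejected), write CSV/JSON reports shaped like the
orientation and organization tables, and record a provenance block (config
hash, seed, package version) beside every output. The thin wrapper at
`inst/cli/guvflim` exposes them as shell commands with exit codes
0/2/3/4 (success / config / no vesicle / fit failure).

```{r workflow, eval = FALSE}
d <- tempdir()
cmd_simulate(list(nu_deg = 38, seed = 11,
                  output_prefix = file.path(d, "run")))
cmd_analyze(list(input_prefix = file.path(d, "run"),
                 output_dir = file.path(d, "reports")))
```

## Known limitations

- Single vesicle per field; no z-stacks, drift correction, or aggregate
  classification.
- The per-image σ_ν is a Poisson counting error only; vesicle-to-vesicle
  variability must come from replicates.
- No IRF deconvolution: lifetimes well below the instrument response are
  outside the intended regime.
- The decay-cube container is multi-page TIFF + JSON rather than a
  hierarchical binary format; it is lossless for counts below 2²⁴ per
  (pixel, bin), which is far beyond any realistic TCSPC occupancy.
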