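# guvflim

Polarized fluorescence-lifetime (FLIM) analysis of single giant unilamellar
vesicles (GUVs): recover the mean orientation of fluorophore transition
dipoles with respect to the membrane normal from a two-channel polarized
confocal image of the vesicle equator, and quantify the organization forms of
amphotericin B (AmB) from TCSPC decay decompositions. A ground-truthed
photon-level simulator makes every stage verifiable without instrument data.

The package is for membrane biophysicists and microscopists working with
linear dichroism / photoselection measurements on single bilayers — e.g.
asking how a sterol (ergosterol vs cholesterol) reorients a membrane-bound
drug — and for method developers who need a reproducible synthetic benchmark
for polarized FLIM pipelines.

## The model

The equatorial ring of a GUV under Y-polarized excitation is weighted by the
photoselection law for dipoles at cone angle ν about the local membrane
normal. With the membrane azimuth integrated out, the sectors perpendicular
to the image axes absorb as

    A_Y(ν) = cos²ν          (left/right sectors, normal ∥ polarization)
    A_Z(ν) = (1 − cos²ν)/2  (top/bottom sectors),

so `A_Y + 2 A_Z = 1`. Fluorescence is absorption × quantum yield, and yield
scales with the amplitude-averaged lifetime `⟨τ⟩ = Σaᵢτᵢ/Σaᵢ` of each
sector's pooled decay, giving the measured ratio and its closed-form
inversion

    R = F_Z/F_Y = T · (1 − cos²ν)/(2 cos²ν),   T = ⟨τ⟩_Z/⟨τ⟩_Y
    cos²ν = T/(2R + T),   ν = arccos √(cos²ν).

`R = 1` at equal lifetimes corresponds to the magic angle (54.74°), which is
also the signature of orientational disorder. Anisotropy and total intensity
use the G-corrected estimators `r = (F∥ − G F⊥)/(F∥ + 2G F⊥)` and
`F = F∥ + 2G F⊥`; time-resolved anisotropy is fit as `r(t) = r₀ e^(−t/θ)`,
and `r₀ = (3cos²β − 1)/5` links the fundamental anisotropy to the angle β
between absorption and emission dipoles.

TCSPC decays are decomposed by Poisson maximum likelihood, either with free
lifetimes or constrained to the AmB organization-form library — tetramer
0.35 ns, parallel dimer 1.8 ns, monomer 3.0 ns, antiparallel dimer 6.8 ns —
reporting amplitude fractions per form.

## Worked example

Simulate a vesicle with the dipole angle and lifetime mixture of an
ergosterol-containing AmB membrane, then run the full analysis:

```r
library(guvflim)

out <- simulate_guv_stack(simulation_config(
  nu_deg = 38,                                          # ground truth
  components = data.frame(tau_ns = c(0.35, 1.8, 6.8),   # AmB forms
                          amplitude = c(39.6, 27.3, 33.1)),
  photons_per_sector = 1e6, seed = 42))

estimate_orientation(out$stack, tau_fit = "library")
#> orientation report (aperture 20 deg)
#> orientation: nu = 38.19 deg (cos^2 nu = 0.6177)
#>   sector ratio R = 0.3152, lifetime ratio T = 1.0185, sigma_nu = 0.03 deg
#>   F_Z = 309829 (360 px, <tau>_Z = 2.93 ns), F_Y = 982888 (360 px, <tau>_Y = 2.877 ns)

organization_report(out$stack)
#> organization forms (3232 ring px, <tau> = 2.880 ns, chi2_red = 0.972):
#>   tetramer              39.47 % +/- 0.15
#>   parallel_dimer        27.50 % +/- 0.11
#>   antiparallel_dimer    33.04 % +/- 0.09
```

Reading the output: the lifetime-weighted sector ratio `R = 0.315` inverts to
`ν = 38.2°` (truth 38°, within the per-image Poisson uncertainty plus the
sub-degree aperture-averaging bias), and the library-constrained fit of the
pooled ring decay returns the three simulated amplitude fractions to a few
tenths of a point with a reduced chi-square of ~1.

Config-driven workflow commands (`cmd_simulate`, `cmd_analyze`,
`cmd_fit_decay`, `cmd_scan_aperture`) write CSV/JSON reports with provenance
blocks; `inst/cli/guvflim` wraps them for the shell. See the methods
vignette (`vignettes/guv-polarized-flim.Rmd`) for the model assumptions,
detection-geometry conventions, fitting details and known limitations.

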