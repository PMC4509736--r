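---
title: "Photon-counting simulation of TIRF and confocal images: models, parameters, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photon-counting simulation of TIRF and confocal images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photonsim)
```

`photonsim` renders fluorophore coordinate trajectories into digital
microscope images whose pixel values are photon counts. This vignette is the
package's own account of the models it implements, the parameters that
matter, the numerical choices behind them, and what the simulations do and
do not capture.

## The simulation chain and its assumptions

The chain has four stages, each a deliberate simplification:

1. **Illumination.** Geometric (intensity-only) optics. The TIRF evanescent
   field is `T_pol · |A_I|² · exp(-z/d)` with penetration depth
   `d = λ/(4π√(n₁²sin²θ − n₂²))` and the standard s/p interface
   intensity-enhancement factors (s: `4cos²θ/(1−n²)`; p:
   `4cos²θ(2sin²θ−n²)/(n⁴cos²θ+sin²θ−n²)`, `n = n₂/n₁`). The intensity
   convention is isolated in one internal function (`tir_enhancement`) so an
   amplitude-coefficient convention can be swapped in without touching
   anything else. The confocal beam is an ideal Gaussian beam with a flat
   wavefront at focus; there is no Gouy phase, no aberration, no speckle.
2. **Emission.** `n_emit = σ δT/(4π) · F · c_conv` per fluorophore:
   absorption at rate `σF`, one emitted photon per `1/c_conv` absorbed
   (default one per million), divided over the unit sphere because the
   detector sits in one direction. No saturation, ground-state depletion,
   photobleaching, blinking, FRET or anisotropy — emission is linear in
   excitation, which is what makes the beam-power linearity tests exact.
3. **Image formation.** Scalar paraxial Born–Wolf PSF,
   `|∫₀¹ J₀(k·NA·r·ρ) exp(−(i/2)kρ²z·NA²/n) ρ dρ|²`, with the `NA²/n`
   defocus scaling of the common paraxial reduction. Dipole orientation
   (a polarized PSF) is out of scope.
4. **Detection.** Monte Carlo per pixel: Poisson shot noise, binomial QE
   thinning (photons stay countable integers), Poisson dark charge, a
   Gamma-distributed EM register, Gaussian read noise, linear A/D with
   floor quantization and clipping.

## Why the PSF is normalized over a finite region

Photon accounting requires `∫ PSF d³r = 1`: the PSF only redistributes a
fluorophore's photons. But the Born–Wolf intensity decays oscillatorily at
its tails, so the infinite-volume constant is numerically treacherous, and a
wrong constant silently rescales every image. The package therefore
normalizes over a finite cylinder `{r ≤ Λ, |z| ≤ Λ}` with `Λ = 1.0 µm` by
default. The region is interpreted as a *cylinder* (radial range × axial
range) rather than a cube, because the two stated ranges are a radial and an
axial one; the cylindrical volume element `2πr dr dz` is what the
trapezoid-rule normalizer integrates. Tests cross-check the integral with an
independent Simpson quadrature to 1e-3.

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `phi_W_per_cm2` (TIRF) | W/cm² | 20 | lowest of the 20–50 benchmark series |
| `theta_deg`, `n1`, `n2` | °, – | 70, 1.52, 1.33 | typical objective-type TIRF, glass/water |
| `Phi_W` (LSCM) | W | 5e-6 | lowest of the 5–100 µW benchmark series |
| `w0_um` | µm | `λ/(π·NA)` | diffraction-limited Gaussian waist |
| `cross_section_cm2` | cm² | 1e-14 | order of magnitude for organic dyes |
| `conversion_factor` | – | 1e-6 | one emission per million absorptions |
| `filter_transmission` | – | 0.55 | dichroic + emission filter survival |
| `Lambda_um` | µm | 1.0 | finite PSF normalization region |
| `dr_um`, `dz_um` | µm | 0.01 | <1e-3 normalization drift on halving |
| `pixel_size_um`/`magnification` | µm, – | 16 / 60 | 0.267 µm object pitch |
| `pinhole_radius_um` | µm (image) | 28.8 | ≈1 Airy unit at M = 60 |
| camera fields | see `?camera_config` | — | placeholders; instrument values are configuration, not truth |

The `collection_efficiency` factor (default 1) lets a user fold objective
solid-angle collection into the emission arithmetic without changing the
equations.

## The sample generators

The generators produce the statistical structure the imaging benchmarks
assume, standing in for a full reaction–diffusion simulator:

* `generate_surface_plate()` — stationary molecules uniform in the field of
  view at z = 0 (immobilized single-molecule assay).
* `generate_solution_box()` — free Brownian dynamics, per-axis displacement
  variance `2·D·dt`, reflective mirror-fold boundaries. Defaults are the
  solution benchmark: 30 × 30 × 6 µm³ at 100 µm²/s. Mirror folding is exact
  for Gaussian steps small against the box.
* `generate_hemisphere_cell()` — a truncated hemispherical cell (sphere of
  radius `diameter/2` centred on the coverslip, cut at `height`; default
  20 µm × 7 µm) with diffusing cytosolic molecules and stationary membrane
  molecules on the spherical cap.

They deliberately omit chemical reactions, state switching, birth/death,
crowding and lattice geometry. Passing tests on these fixtures therefore
show that the *optics and detector* chain is right, not that any cellular
kinetics are.

**A known bias worth stating plainly.** `estimate_diffusion_msd()` fits the
ensemble MSD over the first 10 lags and returns `slope/6`. In the default
solution box the 6 µm z-dimension confines the walk: with `D = 100 µm²/s`
and `dt = 1 ms`, the 10-lag MSD is visibly sub-linear in z (the exact
reflecting-boundary series gives an expected estimate of ≈ 87 µm²/s, and
the acceptance script measures the same), so the estimator recovers the
*apparent* D of the confined geometry, not the free-space input. On a
weakly confined fixture (30 µm cube, small `D·dt`) the same estimator
recovers the input D within a few percent, which is what the unit tests
check. This is physics of the benchmark geometry, not an estimator defect;
use larger boxes or shorter lag windows when free-space D is the target.

## Numerical choices

* **Pupil integral.** Fixed 512-point Gauss–Legendre on ρ ∈ [0, 1]:
  deterministic, vectorizes over the whole (r, z) grid as one complex
  matrix product, and tabulates the default 151 × 301 grid in well under a
  second.
* **Tabulation + bilinear lookup.** Images are formed from the table, not
  from fresh quadratures. Radial queries beyond `r_max` return 0 (defined
  truncation); axial queries beyond `z_max` raise an error — silently
  truncating defocused light would miscount photons, so the caller must
  enlarge the table instead.
* **Pixel integration and supersampling.** A TIRF pixel value is
  `PSF(pixel centre) × pixel area`. At the default 0.267 µm pitch the Airy
  core (first zero at `0.61λ/NA ≈ 0.24 µm` for 578 nm / NA 1.49) is
  under-sampled, and a single molecule's summed counts can depend strongly
  on its sub-pixel position. `expected_image_tirf(..., supersample = s)`
  averages the PSF over an s × s midpoint grid per pixel; `s = 4` brings
  single-molecule totals within a few percent of a dense quadrature and is
  what the photometry test uses. The default stays 1 (centre sampling) so
  the default cost is one lookup per pixel per molecule.
* **Confocal scan.** The scan delta-function is interpreted as one beam
  dwell per output pixel, beam centred on the pixel; sub-pixel scanning is
  out of scope. Excitation is evaluated *at the molecule's position*
  (local excitation), then the molecule's PSF is integrated over the
  pinhole disk of object-space radius `R/M`.
* **Pinhole capture table.** The pinhole integral depends only on the
  molecule's lateral offset from the beam axis and its defocus, so it is
  pre-tabulated as `C(Δ, |z|)` by polar Gauss–Legendre/trapezoid quadrature
  and looked up bilinearly per molecule–pixel pair. This is what makes a
  100 × 100 scan of 1,000 molecules a seconds-scale computation; the full
  19,656-molecule benchmark is the same code, ~20× slower, and the test
  suite exercises the 1,000-molecule subsample.
* **Detector quantization.** A/D conversion floors (never rounds) and
  clips to `[0, 2^bit_depth − 1]`; saturation is flagged in metadata,
  never wrapped. Hardware binning sums charge over b × b blocks *before*
  the single readout-noise draw per binned pixel, matching CCD binning
  semantics. EMCCD dark current is charge and passes through the EM
  register; PMT dark counts are pulses added after QE thinning.
* **Degenerate inputs.** Empty trajectories produce valid empty images;
  `D = 0` freezes the sample; `em_gain = 1` and `QE = 1` are exact
  identities, not degenerate draws; a constant image histograms into a
  single bin.
* **Randomness.** Every stochastic operation takes one integer seed; chains
  fan a master seed into independent per-stage substreams so changing the
  draw count in one stage cannot shift another. All seeded paths are
  bit-reproducible, and the caller's RNG state is restored afterwards.

## Interpretation of ambiguous conventions

Two conventions in the underlying image-formation notation admit multiple
readings, and the package fixes them explicitly:

* The PSF argument coupling molecule position and magnification is
  evaluated entirely in **object space**: detector pixel centres are
  demagnified by M and the PSF is evaluated at object-space offsets. This
  equals image-space evaluation up to the M² area factor, which the
  object-space pixel-area integration absorbs.
* The axial phase convention of the Born–Wolf reduction uses the `NA²/(2n)`
  defocus scaling. A convention differing by an axial scale factor would
  change defocus rates; the choice is isolated in `born_wolf_intensity()`
  for easy replacement (e.g. by a vectorial or Gibson–Lanni model).

Configuration files are YAML — one human-editable key-value file whose
sections (`sample`, `psf`, `tirf`, `camera`, `lscm`, `pmt`, …) mirror the
constructor arguments. Note one YAML quirk handled internally: a bare `n:`
key is YAML-boolean for "no", so the reader maps it back; quoting `"n"` in
files is the safe spelling.

## Problem sizes used in the checks

The test suite and acceptance script run: PSF tabulation at the default
10 nm grid (151 × 301 nodes); a 152 × 156 TIRF frame of 100 surface
molecules; a 100 × 100 confocal scan of a 1,000-molecule subsample of the
solution box; detector-chain moment checks on 10⁴-pixel constant images;
and the 1,000-molecule × 100-frame diffusion benchmark. These sizes were
chosen as the smallest at which each statistical check has the power its
tolerance needs.

## Known limitations

* Intensity-only optics: no polarization-resolved PSF, no aberrations, no
  interference or speckle, single focal plane per run.
* Photophysics is a constant-rate point process: no bleaching, blinking,
  spectra, lifetime or quenching; the 55% filter survival is a per-species
  constant, not a spectral overlap integral.
* Detector models omit clock-induced charge, pixel-response
  non-uniformity, and PMT pile-up/dead time.
* Default camera/PMT numbers are plausible operating points, not any
  specific instrument; calibrating them against a real system is the
  user's task, and the photon-budget log written by `run_simulation()`
  (total expected photons → expected photoelectrons → mean A/D per frame)
  is the hook for doing it.
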