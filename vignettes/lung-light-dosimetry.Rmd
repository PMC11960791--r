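---
title: "Methods: lung optical properties and PDT light dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lung optical properties and PDT light dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `lungoptics`, the
assumptions behind them, the tunable parameters, and the numerical and
design choices made where the problem left the design open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Scientific setting

Interstitial photodynamic therapy (PDT) of peripheral lung cancer delivers
664 nm laser light (the talaporfin sodium activation wavelength) through a
thin side-firing fiber probe placed bronchoscopically so that its emission
region sits at the tumor. Whether the treatment works depends on how light
propagates through lung tissue, which is governed by two wavelength-
dependent coefficients: the absorption coefficient $\mu_a(\lambda)$ and the
reduced scattering coefficient $\mu_s'(\lambda) = \mu_s (1 - g)$, both in
mm$^{-1}$. The package implements the full computational chain from
bench measurements of thin tissue slabs to three-dimensional dose maps:

1. a forward Monte Carlo model of a tissue slab mounted between glass
   slides, predicting the diffuse reflectance $R_d$ and total
   transmittance $T_t$ that a double-integrating-sphere (DIS) system
   measures (`simulate_slab()`);
2. inverse Monte Carlo (IMC): iterating the forward model until it
   reproduces measured $(R_d, T_t)$, yielding $(\mu_a, \mu_s')$ per
   wavelength (`invert_single()`, `invert_spectrum()`);
3. chromophore decomposition of $\mu_a(\lambda)$
   (`fit_mua()`, `correct_saturation()`, `saturation_drift()`);
4. per-wavelength group statistics across tissue types
   (`compare_groups()`, `summarize_groups()`);
5. voxel Monte Carlo light transport from the cylindrical side-firing
   probe in a 3D lung phantom (`build_phantom()`, `run_transport()`);
6. dose-volume reduction of the fields (`cvh()`, `coverage()`).

Because no raw patient spectra are distributed, a synthetic-data module
(`tissue_presets()`, `generate_group()`, ...) generates cohorts with the
statistical structure the analysis assumes, storing its ground truth so
that every stage is tested by recovery rather than by eyeball.

## The chromophore model

Tissue absorption in the visible/NIR is modelled as a linear mixture

$$\mu_a(\lambda) = A e^{-B\lambda} + f_w\,\mu_a^{water}(\lambda)
  + f_b\left[S\,\mu_a^{oxy}(\lambda) + (1-S)\,\mu_a^{deoxy}(\lambda)\right]$$

with $f_b$ the blood volume fraction, $S$ the hemoglobin oxygen
saturation, and $f_w$ the water volume fraction, fixed at 75 % (the
conventional lung value). The exponential term absorbs all Soret-band
chromophores (collagen, porphyrins) into a smooth "dry bloodless tissue"
background with amplitude $A$ (mm$^{-1}$) and rate $B$ (nm$^{-1}$); it is
a proxy, weakest in the Soret region itself, which is why the default fit
window is 450-800 nm (configurable via `fit_range`).

Whole-blood reference spectra are derived from bundled molar extinction
tables assuming 150 g hemoglobin per liter of blood and a molecular weight
of 64 500 g/mol; both constants are exposed in `hb_blood_constants` and
overridable in `chromophore_library()`. The bundled tables are
approximate transcriptions of the standard compiled hemoglobin and water
data sets; their filenames and headers mark them as synthetic
reconstructions (see `inst/extdata/`). Band positions (Soret maxima near
414/434 nm, Q bands near 542/576 nm for HbO$_2$ and 556 nm for Hb) and
red-region magnitudes are preserved, which is what the fitting,
correction and ordering properties rely on. Interpolation onto a working
grid is monotone piecewise-cubic (Fritsch-Carlson) on the log-absorption:
hemoglobin spans decades, and interpolating the logarithm avoids negative
overshoot between knots.

The *saturation correction* used before in vivo dosimetry replaces the
fitted hemoglobin component with the component at a target saturation
(97 % in vivo):
$\mu_a^{corr} = \mu_a + f_b (S_{target} - S_{fit})
(\mu_a^{oxy} - \mu_a^{deoxy})$. It touches nothing but the hemoglobin
term, and correcting to $S_b$ and back to $S_a$ restores the input to
machine precision (tested).

### Fitting

`fit_mua()` uses bounded Levenberg-Marquardt least squares
(`minpack.lm::nls.lm`) on unweighted residuals. The product $f_b S$
creates a ridge; the optimizer is therefore multi-started from the four
corners of a plausible $(S, f_b)$ rectangle and the lowest-RSS solution is
kept. When $\hat f_b$ collapses to zero, $S$ is unidentifiable (it enters
only multiplied by $f_b$) and the fit is flagged, never silently reported.

## Forward slab Monte Carlo and inversion

The DIS sample is modelled as a laterally infinite tissue slab between two
clear glass slides in air, illuminated by a collimated normal-incidence
beam. Packet-weight Monte Carlo follows the multi-layer conventions of
the classic layered-tissue codes: Henyey-Greenstein phase function,
implicit absorption weighting, Fresnel reflection/refraction at every
index step, Russian roulette (threshold $10^{-4}$, survival 1/10). The
specular reflection of the incident beam at the entry interfaces is
computed analytically and excluded from $R_d$ by default (diffuse
reflectance only; `include_specular` toggles it). Weight bookkeeping is
exact: launched = $R_d$ + $T_t$ + absorbed + net roulette flow, to
machine precision every run (tested, not just in expectation).

Fixed parameters follow the measurement convention for lung tissue:
$g = 0.9$, $n = 1.38$, glass $n = 1.52$ with 1 mm slides (the slide glass
constants are not part of the measurement record; they are documented,
configurable defaults). Lateral losses and sphere-port corrections are
out of scope: the slab is laterally infinite.

The RNG is a self-contained xoshiro256++ seeded by splitmix64, so a given
seed reproduces a run bit-for-bit regardless of R's RNG state.

Validation uses two independent routes: a published exact benchmark
(total reflectance 0.2600 for albedo 0.9, isotropic scattering, relative
index 1.5, semi-infinite medium) and a frozen comparison against a
separately written analog (unweighted) Monte Carlo implementation with a
different RNG, for the glass-mounted anisotropic case.

### Inversion

`invert_single()` finds $(\mu_a, \mu_s')$ whose forward simulation
reproduces measured $(R_d, T_t)$:

- a coarse precomputed lookup table (log-spaced $7 \times 7$ grid,
  cached per slab geometry) supplies the starting point;
- damped Newton iterations on the $2\times2$ finite-difference Jacobian
  refine it, in $\log(\mu_a), \log(\mu_s')$ coordinates (positivity and
  better conditioning), with steps clipped to one log-unit;
- all forward evaluations within a Newton stage share one seed (common
  random numbers), so the solver sees a smooth deterministic map and
  converges to solver precision despite the stochastic kernel;
- stages run at $10^4$ packets, then $10^5$ packets for the final
  refinement whose residual is reported.

The tolerance is 0.2 % absolute on both $R_d$ and $T_t$, below the 0.8 %
accuracy of the DIS measurement the inversion serves. Measurements with
$R_d + T_t > 1$ or $T_t$ above the clear-slab transmittance (computed
analytically from the interface stack) are rejected as unreachable.
Non-convergence is flagged per wavelength and never silently dropped.
`invert_spectrum()` warm-starts each wavelength from its neighbour's
solution, which only changes iteration counts, not converged answers
(tested). The exact iteration schedule of the original instrument
software is not public; this lookup-plus-Newton design is the package's
own, chosen for robustness at the stated tolerance.

## Phantom and voxel transport

`build_phantom()` voxelizes the reference treatment geometry: a 30 mm
cube of homogeneous surrounding tissue at 0.05 mm isotropic voxels, a
10 mm spherical tumor at the center, and a 1 mm air bronchus through the
center along z. Labels are assigned by cell-centered center-in-shape
tests with precedence air > tumor > surrounding. Coordinates are 0-based
voxel indices with the origin at the domain corner; the bronchus axis is
z (the reference figure names no axes; this is a documented convention).
The bronchus traverses the whole domain rather than terminating at the
tumor - whether it should terminate is not specified, and full traversal
is the simpler, symmetric choice. The probe itself is not voxelized; it
exists only as a source surface, since probe shadowing is not part of the
model.

Air properties are $\mu_a = 10^{-5}$ mm$^{-1}$, $\mu_s' = 0.1$ mm$^{-1}$,
$n = 1$, $g = 1$. $g = 1$ is handled as a forward delta - scattering
events leave the direction unchanged - avoiding the degenerate
Henyey-Greenstein case (for a forward delta any $\mu_s$ value is
physically equivalent; the tabulated value is used unchanged rather than
dividing by $1 - g = 0$).

`run_transport()` samples free paths in optical depth and converts them
voxel-by-voxel through the local attenuation, so packets keep their
unconsumed optical depth across voxel faces (memoryless and unbiased).
Fresnel reflection/refraction applies only across faces where $n$ changes
(tissue-air); tissue-tissue faces are index-matched. The domain boundary
is absorbing, with escaped weight tallied. Fluence is scored with the
track-length estimator (lower variance than collision scoring at these
albedos) and scaled by the delivered energy; the energy-deposition field
is *derived* as $\mu_a \times$ fluence per voxel, making that identity
exact by construction rather than a second noisy estimate. Simulations
are single-threaded and bit-reproducible per seed.

The source models the clinical side-firing diffuser: a 1 mm diameter,
11 mm long cylindrical surface centered at the tumor center, uniform in
area, with a cosine-weighted angular profile about the outward radial
normal, delivering 150 mW for 667 s (100.05 J). The true angular profile
of the clinical probe is proprietary to its design; cosine-weighted
radial emission is the documented substitute. Packets launch from the
cylinder surface regardless of the underlying voxel label (the probe sits
in the bronchus).

Physics oracles in the test suite: exact energy bookkeeping per run;
deposited + escaped energy equal to delivered energy within Monte Carlo
error; Beer-Lambert decay of an unscattered pencil beam; and
shell-averaged point-source fluence in a homogeneous medium matching the
diffusion form $e^{-\mu_{eff} r}/r$, $\mu_{eff} = \sqrt{3\mu_a(\mu_a +
\mu_s')}$, over 2-8 mm, cross-checked during development against a
separate analog random-walk implementation.

## Group statistics

`compare_groups()` applies the classical equal-variance Student unpaired
two-tailed t-test per wavelength (via `stats::t.test`), separately for
$\mu_a$ and $\mu_s'$, with $\alpha = 0.01$ masks. No multiplicity
adjustment is applied - the intended reading is a raw p-value versus
wavelength plot - so isolated sub-threshold p-values among ~200
wavelengths are expected under the null; the masks should be read as
descriptive, not confirmatory. Summaries report mean ± sample standard
deviation ($n-1$) at the PDT wavelengths 630/635/664/690 nm, and
`cv_report()` gives the inter-sample sd/mean at a reference wavelength.

## What the synthetic cohort emulates

`tissue_presets()` encodes one generator specification per tissue type
(normal, carbon-deposited, tumor human lung; normal porcine lung):

- $\mu_a$ truth from the chromophore model with the mean fitted
  parameters per tissue (normal: $f_b$ 3.9 %, $S$ 65 %; tumor: $f_b$
  2.0 %, $S$ 46 %; carbon and porcine: deoxygenated-leaning mixtures).
  The dry-background amplitude is *calibrated* with
  `calibrate_dry_amplitude()` so the model mean hits the measured group
  mean $\mu_a(664)$ (0.37 / 0.83 / 0.27 / 0.26 mm$^{-1}$). Taking the
  reported mean $A$ and $B$ verbatim instead would overshoot the measured
  $\mu_a(664)$ by ~40 % - the reported $A$ has a $\pm 100$ % spread, and
  the calibrated values sit comfortably inside it - so the anchor chosen
  is the measured absorption, which is what the downstream dosimetry
  consumes. The carbon preset emulates carbon deposition with a nearly
  flat, high background ($B = 5\times10^{-4}$ nm$^{-1}$): graphitic
  absorption is spectrally flat compared to hemoglobin.
- $\mu_s'$ truth from the standard tissue power law
  $a(\lambda/500)^{-b}$ (monotone decreasing), with $a, b$ calibrated so
  $\mu_s'(664)$ and the 630-690 nm trend match the measured summaries.
- Inter-sample variability: lognormal multiplicative draws on the
  positive amplitudes ($f_b$, $A$, $a$) at the reported per-tissue
  coefficients of variation (40/37 % normal, 21/7 % carbon, 30/21 %
  tumor for $\mu_a$/$\mu_s'$; 19/30 % porcine from the reported
  sd/mean), truncated-normal draws for $S$ (a bounded fraction, for
  which a lognormal would be inappropriate), and a mild 5 % jitter on
  the scattering power for variable cohorts.
- Measurement noise: multiplicative lognormal per wavelength
  (`noise_cv`); DIS plumbing adds optional 0.8 % noise on $R_d/T_t$,
  the stated instrument accuracy.
- Cohort sizes default to the measured ones (23 / 3 / 15 / 12).

What it does **not** emulate: patient-level clustering (replicates from
one patient treated as independent, as in the measured cohort),
wavelength-correlated instrument drift, sphere-port losses, inflation
state of the lung, and any real covariance between absorption and
scattering amplitudes. Passing recovery tests therefore demonstrate
correctness of the estimators under the stated noise model, not
robustness to every artifact of real DIS spectra.

## Problem sizes and runtime choices

The package's own test and analysis configurations are chosen to resolve
the quantities they check while staying desk-scale: slab simulations use
$10^4$-$10^5$ packets during inversion ($2\times10^5$-$10^6$ for oracle
comparisons); scenario transport runs use a 0.15 mm grid ($200^3$ voxels)
with $10^6$ packets, and the conservation oracle a 0.3 mm grid with
$10^6$ packets. The reference configuration (0.05 mm, $10^9$ packets) is
expressible through the same API (`build_phantom()` defaults,
`n_packets`) for full-scale runs. Monte Carlo standard errors are
reported alongside every estimate so that scaled-down runs remain
interpretable; dose-volume fractions at the 0.1-100 decade thresholds
stabilise far below $10^9$ packets.

## Known limitations

- The bundled chromophore tables are smooth reconstructions, adequate
  for band structure and red-region contrast but not a metrological
  reference; swap in measured tables via the documented file format for
  quantitative work beyond the red/NIR.
- The slab model ignores lateral losses and sphere corrections, so
  simulated $R_d/T_t$ correspond to an idealized DIS system.
- The exponential dry-background proxy biases fits if the window
  includes the Soret region; keep `fit_range` at or above ~450 nm.
- Voxelized interfaces rasterize the bronchus wall; Fresnel normals are
  axis-aligned, which is accurate at 0.05-0.15 mm voxels for a 1 mm
  cylinder but would degrade for much coarser grids.
- The tumor is a perfect sphere; irregular tumors (shadowing,
  heterogeneous uptake) are outside the geometry model.
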