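---
title: "Simulating photoacoustic lifetime imaging of tissue oxygen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating photoacoustic lifetime imaging of tissue oxygen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement this package simulates

Photoacoustic lifetime imaging (PALI) estimates tissue oxygen partial
pressure (pO2) from the decay rate of the methylene-blue (MB) triplet
state. A 660 nm pump pulse promotes ground-state MB monomers into the
long-lived triplet state; an 830 nm probe pulse, fired a delay tau later, is
absorbed by whatever triplet population remains and launches an acoustic
wave whose amplitude is proportional to that population. Sweeping tau and
fitting the amplitudes with a decaying exponential yields the triplet decay
rate `kt`, and the Stern-Volmer relation

    kt = kQ * pO2 + k0

converts it to oxygen. Because collisional quenching by oxygen dominates
triplet de-excitation, `kt` moves by roughly a factor 30 between anoxic
(1.84e4 1/s) and air-saturated (6.05e5 1/s at 150 mmHg) solutions, the rates
the package uses for its default two-point calibration
(`default_stern_volmer()`: kQ = (6.05e5 - 1.84e4)/150, k0 = 1.84e4).

The practical question the simulation addresses is imaging depth: light at
both wavelengths is attenuated by tissue scattering and absorption, so the
photoacoustic signal from a dye-loaded lymph node shrinks roughly as
`exp(-(mu_eff_660 + mu_eff_830) * d)` with node depth `d`, and at some depth
the fitted rates become too noisy to convert into a clinically meaningful
oxygen value.

## Model chain and assumptions

`simulate_forward()` composes the forward model once per phantom and
oxygenation:

1. **Light transport.** A photon-packet Monte Carlo (`monte_carlo_fluence()`,
   compiled) with Henyey-Greenstein scattering (g = 0.9, mu_s = mu_s'/(1-g)),
   continuous absorption weighting, track-length fluence estimation, Russian
   roulette (threshold 1e-4, survival 0.1), and index-matched boundaries.
   The background medium uses neck-tissue optics: mu_a = 0.22 / 0.235 1/cm
   and mu_s' = 9.1 / 7.3 1/cm at 660 / 830 nm. The spherical node (default
   radius 3 mm, 400 uM MB) adds the ground-state monomer absorption at
   660 nm; only the monomer half of the dye (`monomer_fraction()`, 50% at
   400 uM with k_dim = 2500 1/M) is photoactive.
2. **Triplet pumping.** Per node voxel, the pumping rate is
   `beta = eta * sigma_g * phi / (h nu)` with `phi` the local fluence rate,
   and the end-of-pulse triplet concentration is
   `nt = beta n/(alpha+beta) (1 - exp(-(alpha+beta) t))` for a 5 ns pulse.
   With 10 mJ/cm^2 at the surface the node top saturates (`beta t ~ 6`).
3. **Probe absorption update.** The probe-wavelength absorption inside the
   node is raised by `ln(10) * eps_T * nt` (decadic extinction converted to
   a natural coefficient — molar extinctions are conventionally decadic
   while the transport and pressure models need base-e coefficients).
4. **Acoustics.** Initial pressure `p0 = Gamma * mu_a * phi_830` (0.2
   default Grueneisen; 1 J/cm^3 = 1 MPa, maps stored in kPa), projected to a
   focused 5 MHz single-element transducer by time-of-flight with 1/r
   spreading, a cos(theta) obliquity factor, a hard aperture cone, and a
   zero-phase Gaussian band-pass (fractional bandwidth 0.6) as the element
   response. This replaces a full-wave acoustic solver: the decay-rate
   estimate depends on relative amplitudes across delays, not waveform
   fidelity, and acoustic attenuation is neglected throughout. The element
   is placed on the beam axis with its 25 mm focus at the node center, so
   depth dependence is purely optical.
5. **Acquisition.** `acquire_dataset()` builds, per delay of the 12-point
   logarithmic schedule (0.5-1000 us), 100 pump+probe and 100 pump-only
   frames with per-frame lognormal pulse-energy jitter (2% SD) and additive
   Gaussian receiver noise of standard deviation NEP; the correction chain
   is energy normalization, frame averaging, pump-artifact subtraction,
   subtraction of the longest-delay corrected trace (the triplet has fully
   decayed there, so this removes the non-decaying background), and
   amplitude extraction.

## Parameters that matter

| parameter | default | units | note |
|---|---|---|---|
| tissue mu_a (660/830) | 0.22 / 0.235 | 1/cm | neck tissue |
| tissue mu_s' (660/830) | 9.1 / 7.3 | 1/cm | neck tissue |
| anisotropy g | 0.9 | - | only mu_s' is constrained by tissue data |
| pump / probe fluence | 10 / 15 | mJ/cm^2 | surface values |
| beam radius | 5 | mm | config value |
| MB concentration | 400 | uM | ~50% monomers |
| eta (triplet yield) | 0.52 | - | literature-typical MB |
| sigma_g at 660 nm | 3.63e-16 | cm^2 | from eps660 ~ 9.5e4 1/(M cm) |
| eps_T at 830 nm | 1.4e4 | 1/(M cm) | literature-typical MB |
| pump pulse | 5 | ns | Q-switched OPO scale |
| transducer | 5 MHz, f=25 mm, D=12.7 mm, bw 0.6 | | config values |
| speed of sound | 1540 | m/s | |
| delays | 12, log, 0.5-1000 | us | |
| frames per delay | 100 + 100 | | pump+probe / pump-only |
| replicates | 7 | | per (depth, pO2) cell |
| NEP | auto | trace units | recorded SNR 100 at the shallowest depth |

The MB photophysical constants (eta, sigma_g, eps_T, k_dim) are not uniquely
fixed by published PALI work; the defaults are literature-typical values for
aqueous MB, shipped in `inst/extdata/mb_constants.yaml` and overridable
everywhere. They scale the absolute signal but cancel out of the decay-rate
estimate; their main observable effect is through self-shielding (the node's
own absorption limits how deep light penetrates it).

## Estimator choices

**Amplitude extraction.** Amplitudes are peak-to-peak, with the peak and
trough sample positions located once on the shortest-delay averaged trace
(highest SNR) and reused at every delay. A max/min rescan per delay would
add a positive bias of order 5-6 noise SDs to weak amplitudes (extreme-value
statistics over the gate), which flattens slow decays and collapses fitted
rates; the fixed-position estimator is linear in the trace, so noise enters
amplitudes with zero mean.

**Background subtraction.** In the pipeline the longest-delay corrected
*trace* is subtracted before extraction, which makes noiseless corrected
amplitudes exactly proportional to `exp(-kt tau)`. The amplitude-level
variant (`subtract_background()`) is provided for user-supplied decay
tables; its residual `A exp(-kt tau_max)` bias is negligible when
`kt tau_max >> 1` (it is 1e-8 even for the anoxic rate).

**Decay fitting.** `fit_decay()` normalizes amplitudes to the earliest
delay and measures time from it, so the double model
`a exp(-b t) + (1-a) exp(-c t)` can satisfy its unit-sum constraint
exactly (the shift redistributes weights but leaves rates unchanged).
Levenberg-Marquardt (minpack.lm) with bounds a in [0,1], rates in
[1e2, 1e8] 1/s; starts from log-linear slopes of the head and tail thirds.
`model = "auto"` keeps the double fit when an F-test at alpha = 0.05
prefers it; for a double fit the *slower* rate is reported (the slow
component tracks the triplet lifetime), and a collapsed mixing weight
(a within 0.01 of 0 or 1) falls back to the dominant component's rate with
a degeneracy flag.

The depth sweep (and every fit of simulated acquisitions in the package's
own validation) uses `fit_model = "single"`: the simulated frames are
generated with a single exponential, and automatic selection on noisy data
accepts a spurious second component whose slower rate is then an outlier
unrelated to the physics being swept. The false-selection rate is well
above the F-test's nominal 5% because the reference-trace subtraction
correlates the residuals across delays, which unweighted least squares
does not model. Auto selection remains the right choice for experimental decays with
possibly biexponential chemistry (for example the anoxic flash-photolysis
transients).

**NEP calibration.** With `nep = "auto"` the per-frame noise SD is set so
the *recorded* SNR — measured on the fully corrected averaged trace, whose
per-sample noise RMS is `2 nep / sqrt(n_averages)` — is ~100 at the
shallowest swept depth. The absolute instrument NEP of the original
apparatus is not published, so depth limits produced by this package are
meaningful relative to this documented noise scale, not as absolute depths.

## What the depth sweep shows, and a structural caveat

With recorded SNR 100 at 4 mm, the two-way optical attenuation
(`mu_eff_660 + mu_eff_830 ~ 4.8 1/cm`) costs a factor ~4.2 per 3 mm step,
so the responsive regime ends near 10-13 mm; beyond it the fits rail at
their rate bounds. Two consequences are worth stating plainly:

* The per-oxygenation *dispersion* of recovered rates grows with depth only
  while the signal remains detectable; past the SNR cliff railed fits
  cluster and the SD collapses again.
* The 10 mmHg clinical error threshold is a fixed *absolute* rate error
  (10 kQ = 3.9e4 1/s) for every oxygenation: it is a 6.5% relative error at
  150 mmHg but a 213% error at 0 mmHg — and the dominant low-SNR failure
  mode at 0 mmHg (rate collapse toward zero) maps to at most
  `k0 / kQ = 4.7` mmHg. Under this noise model the anoxic sweep therefore
  cannot cross the 10 mmHg threshold from below, and the oxygenated sweep
  always crosses first. The ordering of the two clinical depths reported by
  the original experiments (anoxic failing shallower) is produced by an
  upward-scattering failure mode of their (unspecified) estimator that this
  package's documented estimator does not share; the package reports both
  criteria and their brackets so either behavior is visible in the output.

## Problem sizes and numerical choices

Default sweep discretization is 0.4 mm voxels on a 40 x 40 x 35 mm grid
with 1e5 photon packets per Monte Carlo run, seven replicates, five-figure
reproducibility from a single master seed (per-stage seeds are derived by a
fixed integer recurrence; the Monte Carlo uses an internal xoshiro256++
generator so results are independent of R's RNG state). The diffusion-slope
validation uses a quasi-planar geometry (64 x 64 x 24 mm slab, 28 mm beam
radius, 0.8 mm voxels) because the mu_eff asymptote is a one-dimensional
result; at 1e6 photons the fitted on-axis log-slope over 5-15 mm agrees
with `sqrt(3 mu_a (mu_a + mu_s'))` to within a few percent. Energy
conservation of the transport core is tracked exactly (launched + roulette
gains = absorbed + escaped + terminated, to double precision roundoff).

Degenerate inputs are handled without exceptions where a flag is more
useful: inversion of a rate below k0 clamps to 0 mmHg with a `clamped`
attribute; constant-amplitude fits rail at the lower rate bound with a
`degenerate` flag; a noiseless SNR is reported as `Inf`.

## Known limitations

* No acoustic attenuation, speckle, or full-wave propagation; the
  transducer model is far-field and the 1/r weight is clamped at one voxel
  near the element.
* No photobleaching, singlet-oxygen chemistry, or additional triplet
  reactants; dimers only reduce the photoactive concentration.
* Refractive-index-matched boundaries (no Fresnel reflection).
* Absolute depth limits depend on the NEP scale, which is a configuration
  choice, not a measured instrument property.
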