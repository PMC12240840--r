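---
title: "Models and methods behind vesiq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vesiq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

vesiq analyses time-lapse fluorescence movies of extracellular
neurotransmitter sensors and ships a generative model of the same
physics so that every estimator can be validated against ground truth.
This vignette is the package's account of that model: what it assumes,
how its parameters were chosen, which numerical conventions it uses,
and where its physics knowingly stops short of the biology.

## The generative model

### Release

Each stimulation pulse releases an integer number of vesicles at each
release site, drawn i.i.d. from a categorical distribution over
0–6 quanta (`quanta_dist()`). The control preset uses
`(0.20, 0.60, 0.15, 0.04, 0.01)`, i.e. a release probability of 0.80
and a mean of 1.325 vesicles per successful pulse, with occasional
3–4-vesicle events — the statistics reported for serotonergic synapses.
In *amplitude mode* a trial's response is simply
`quanta x q_true + noise` with `q_true = 0.45`% ΔF/F₀ per vesicle; this
is the fast path used by most quantal-analysis tests. In *movie mode*
each vesicle injects `amount_per_vesicle` (nM µm²) of transmitter into
the concentration field as a sub-pixel Gaussian of width `r_syn / 2`.

### Diffusion and clearance

The concentration field obeys

$$\partial C/\partial t = \nabla\cdot(D\,\nabla C) - k(x,y)\,C + S(x,y,t)$$

on a square grid. Clearance is zone-dependent around the nearest
release site: zero inside the synaptic cleft (`r < r_syn = 0.25` µm,
transporters are perisynaptic, not cleft-resident), `k_peri` in the
perisynaptic annulus out to `r_peri = 3` µm, and `k_extra = k_peri/4`
beyond. With `D_eff = 5` µm²/s and `k_peri = 8.889` s⁻¹ the quasi-steady
spread length `sqrt(D/k_peri)` is 0.75 µm. Transporter inhibition
(SSRI) multiplies all rates by `ssri_factor` (0.2 in the `ssri` preset)
and opens outlet wedges — angular sectors in which clearance is further
reduced by `k_factor` — modelling discrete egress channels.

The profile geometry (16 × 16 µm, dx = 0.1 µm) runs at a
nondimensionally scaled-down diffusivity: physical D for serotonin is
two orders of magnitude larger, but scaling D and k together preserves
every spatial profile while cutting the explicit-integration cost. The
volume geometry (64 × 64 µm, dx = 0.5 µm) exists to ask whether
transmitter reaches a detector tens of microns away; there the *ratio*
of transit time to stimulus-train duration matters, so it runs at
physical scale (`D_eff = 100` µm²/s, `k_peri = 177.8` s⁻¹, same 0.75 µm
spread length) with a weak far-field rate of 0.6 s⁻¹. A slow-D far
field would make a 5-pulse 64 Hz train and a 20-pulse 2 Hz train
indistinguishable at the detector, erasing the synchrony coding the
volume mode is meant to expose.

### Sensor

Per pixel the bound-sensor fraction follows
`dB/dt = k_on C (1 - B) - k_off B` and the reported signal is
`f_max B`. The preset sensor has `k_off = 1/8` s⁻¹ (the 8 s decay time
constant of evoked responses) and `Kd = k_off/k_on = 1010` nM,
matching the default calibration curve. Because `k_on C` is far below
`k_off` outside sub-millisecond release spikes, the sensor operates as
a slow integrator of transmitter exposure: trace rise time is set by
clearance kinetics near the site, decay by `1/k_off`, and single-pulse
amplitudes stay linear in quanta (the equally spaced amplitude peaks
quantal analysis requires). `amount_per_vesicle = 21357` nM µm² is the
one calibrated constant: it makes a single vesicle produce a 0.45%
ΔF/F₀ amplitude in a 0.5 µm ROI, tying movie mode to the
amplitude-mode quantal size.

A consequence worth knowing: an integrating sensor necessarily reports
a larger amplitude when clearance weakens (more exposure reaches it),
so movie-mode quantal size grows by tens of percent under the `ssri`
preset even though the release statistics are unchanged. The empirical
observation that reuptake inhibitors leave amplitude untouched while
prolonging decay cannot be reproduced by any single-compartment model
with a sensor slow enough to produce the 8 s decay; amplitude-mode
generation (where q is a parameter) is the supported way to model
"release unchanged" experiments.

### Camera

`render_camera()` applies `F = F0 (1 + ΔF/F₀/100)`, a Gaussian PSF, a
lognormal baseline field (mean `f0_mean`, CV 0.3 — ΔF/F₀ must be and is
independent of F₀), Poisson shot noise at `photon_gain` photons per
fluorescence unit, and Gaussian read noise. All stochastic stages draw
from independent named streams derived from one root seed
(`stream_seed()`), so changing the shot-noise realisation never
perturbs the sampled quanta.

## Numerical choices

* **Integration** is explicit Euler for diffusion with the stability
  bound `dt <= dx²/(4 D)` enforced at configuration time, combined with
  an exact exponential update for clearance (operator splitting), which
  keeps the scheme stable for arbitrarily large clearance rates. Output
  frames are sub-step averages, so time integrals of the field are
  exact at frame resolution.
* **Variable diffusivity** uses harmonic-mean face values in flux form
  (conserves mass with spatially varying D).
* **Radial profiles** report each annulus at the mean radius of its
  pixels rather than the bin midpoint; on an ideal exponential cone at
  dx = 0.1 µm this keeps the profile within 2% of the function.
* **The exponential spatial fit** fixes the offset at the map's robust
  background (free offsets are degenerate with λ on short profiles) and
  uses Levenberg–Marquardt with log-linear starting values; fits at the
  parameter bounds are flagged, never silently returned.
* **The lattice quantal estimator** scans `q` over
  `[0.4, 1.6] × median(success amplitudes)` (1200 points) and refines
  the chosen point to full precision. Two anti-aliasing safeguards keep
  it on the fundamental spacing: a `q/2` lattice folds residuals and
  can never score worse than `q`, so among spacings within 50% of the
  minimum residual the largest is taken; and sub-half-median successes
  (gray-zone events near the 2.5 σ threshold, the only points a
  sub-harmonic fits better) are excluded from the lattice fit while
  still counting toward the release probability.
* **Noise SD** defaults to the robust SD of the failure cluster,
  iterating classification and re-estimation; with no identifiable
  failures the series is treated as all-successes.
* **Detection** thresholds local maxima of the pixel-max map at
  `background + 4 × 1.4826 × MAD` (background statistics from the lower
  half of map values), merges peaks closer than 1.5 µm keeping the
  larger, and flags sites with a neighbour within 3 µm as not isolated.
  A numerical floor (10⁻⁹ of the dynamic range) prevents floating-point
  dust from registering as peaks on noiseless maps.
* **Outlet counting** normalises each pixel by the radial mean profile
  at its radius before angular binning (outlets are multiplicative
  excursions above the isotropic decay; raw angular means inherit
  grid-dependent radial weighting), estimates the angular spread from
  sub-median bins so broad outlets do not inflate their own threshold,
  and additionally requires 5% contrast over the angular median.

## Preset calibration and known tensions

The presets were calibrated once, before the test suite was frozen, to
reproduce the printed phenotypes of serotonergic transmission; where
the physics cannot meet a phenotype we document the gap rather than
bend the estimator.

* **Spread length.** The control preset's fitted λ on the profile
  geometry is ≈ 0.67–0.76 µm across quanta realisations, consistent
  with the printed ~0.75 µm. The 2-D quasi-steady profile is a Bessel
  K₀, slightly steeper than a pure exponential, so the fitted λ sits
  systematically below `sqrt(D/k)` and the bias grows with λ: at
  `sqrt(D/k)` ≥ 1 µm it exceeds 0.1 µm. Sensor saturation at the site
  centre partially compensates under the control preset.
* **FWHM.** A profile whose exponential fit gives λ = 0.75 µm has a
  half-maximum width of at least `2 ln 2 × λ ≈ 1.0` µm — the package
  measures ≈ 1.1 µm — and *no* smooth saturating transform of the same
  field can make it 0.5 µm while λ stays 0.75 µm. A 0.5 µm figure for
  this profile corresponds to its half-width at half maximum
  (`ln 2 × λ = 0.52` µm), not the full width.
* **SSRI anisotropy.** Narrow low-clearance wedges cannot double the
  half-max aspect ratio in this PDE: lateral diffusion drains a wedge
  at rate `~D/(w/2)²`, which exceeds the clearance it removes at the
  half-max radius, and sensor saturation further circularises the
  mask. The `ssri` preset therefore shows outlet channels clearly in
  the angular profile (counted exactly) and a modest (~10–30%)
  elongation, not a doubling.
* **Band fractions.** `band_integrals()` normalises by the total over
  0–8 µm, so the three bands always sum to 1. Published "relative
  integration" values for this kind of profile sum to more than 1 and
  therefore use a different (unstated) normalisation; the absolute,
  background-subtracted mid-band integral is the quantity that grows
  monotonically as clearance weakens, and that is what the property
  tests assert.
* **Detection at extreme thresholds.** The pixel-max of a shot-noise
  movie has extreme-value statistics: its tail sits several robust SDs
  above the map median at any photon gain, so a 4-robust-SD threshold
  admits occasional false peaks on noisy scenes no matter how bright
  the true sites are. Perfect precision is a property of structured
  noise-free scenes (baseline heterogeneity and PSF, shot noise off);
  under full shot noise the package still attains perfect recall at
  realised SNR ≥ 8 and site count should be read jointly with the SNR
  column.
* **Distal detector.** With purely first-order (non-saturable)
  clearance, the overlapping perisynaptic zones around a site cluster
  absorb ~99% of released transmitter, so far-field peaks are of order
  1 nM — far below a real electrode's limit of detection. The
  detector's default limit (0.6 nM) is chosen to separate synchronous
  multi-axon high-frequency release from single-axon or low-frequency
  release under the volume preset; absolute far-field concentrations
  are not comparable to published voltammetric values and are not a
  goal.

## Problem sizes

The shipped tests and the acceptance script run the profile geometry at
160 × 160 pixels (dx = 0.1 µm) with 10-pulse 16 Hz trains, property
sweeps on an 8.2 µm mini-geometry (41 × 41), volume runs at dx
0.8–1 µm, 40–400-trial amplitude series, and 100–200-replicate
property loops — sizes chosen so the full suite completes in a few
minutes while every tolerance is still binding.

## What the generator does not model

Three-dimensional tissue tortuosity and cleft geometry (the 2-D model
under-weights dilution, which is why movie-mode amplitudes respond to
clearance more strongly than real recordings do); Michaelis–Menten
transporter saturation (clearance is linear, so strong stimulation
cannot overwhelm reuptake); electrochemical physics of voltammetric
electrodes (emulated as a filtered threshold detector); and
photobleaching or motion artefacts. Passing tests demonstrate that the
estimators recover the generative truth of *this* model at realistic
noise levels — not that the model captures every property of brain
tissue.
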