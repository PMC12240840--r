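# vesiq

Quantal and spatial analysis of fluorescent neurotransmitter-sensor
imaging, with a synthetic reaction–diffusion movie generator for ground
truth.

## The problem

Genetically encoded sensors such as the GRAB family report extracellular
neurotransmitter (here: serotonin) as a fractional fluorescence change
ΔF/F₀ in time-lapse movies. From such movies one wants to answer, per
releasing synapse:

* **How much is released?** Classic quantal analysis: per-trial response
  amplitudes fall on a lattice of equally spaced peaks. The spacing *q*
  (quantal size, % ΔF/F₀ per vesicle), the release probability
  *P*ᵣ (successes / trials at threshold *k*·σ), and the vesicular quanta
  per trial `max(1, round(Aᵢ/q))` summarise release. *q* is estimated by
  minimising the lattice residual
  `L(q) = Σᵢ (Aᵢ − round(Aᵢ/q)·q)²` with anti-aliasing safeguards against
  the q/2 sub-harmonic.
* **How far does it spread?** The pixel-wise maximal ΔF/F₀ map around an
  isolated release centre is radially averaged and fitted with
  `p(r) = p₀·e^(−r/λ)`; λ is the spatial spread length constant. The
  half-maximum contour yields FWHMs, aspect ratio and roundness; angular
  profiling counts egress outlets; radial band integrals quantify
  synaptic (0–0.5 µm), perisynaptic (0.5–3 µm) and extrasynaptic
  (3–8 µm) accumulation.
* **What concentration is that?** A Hill sigmoid
  `F = f_max·Cʰ/(Cʰ + EC50ʰ)` calibrates ΔF/F₀ against concentration and
  is inverted analytically.
* **Synaptic or volume transmission?** A distal low-pass point detector
  (an emulation of a voltammetric electrode tens of microns away)
  classifies episodes by whether transmitter escapes the neuropil.

Because no public dataset accompanies this kind of experiment, the
package ships a first-class generator: categorical vesicular quanta per
pulse, 2-D diffusion with zone-dependent first-order transporter
clearance (`∂C/∂t = ∇·(D∇C) − k(x,y)·C + S`), optional SSRI-weakened
clearance with angular outlet wedges, first-order sensor binding
kinetics, and a camera model (PSF, lognormal baseline field, Poisson
shot noise). Every analysis stage is tested against this ground truth.

## Worked example

```r
library(vesiq)

# 40 quantal trials at a control synapse: q_true = 0.45% dF/F0 per
# vesicle, release probability 0.80, amplitude noise sd = 0.1 q
site <- release_site(8, 8, q_true = 0.45)
amps <- generate_amplitude_series(site, make_protocol(40, 0.1),
                                  noise_sd = 0.045, seed = 7)
qa <- quantal_analysis(amps$amplitude_pct)
qa
#> <quantal_result> q = 0.472% dF/F0, Pr = 0.725, avg quanta (successes) = 1.276, max = 3
#>   29/40 successful trials, sigma_noise = 0.0423%

dff_to_concentration(calibration_curve(), qa$quantal_size_q)
#> [1] 105.386
```

The estimated quantal size (0.472% ΔF/F₀) recovers the generative 0.45%
within 5%; the success rate 0.725 matches this draw's realised release
probability exactly (29 of 40 trials released at least one vesicle); and
the default calibration converts the quantal amplitude to roughly
100 nM of transmitter at the release site.

Movie-level analysis follows the same grammar — `simulate_concentration()`
→ `apply_sensor()` → `render_camera()` → `compute_dff()` →
`compute_pixel_max_map()` → `detect_release_sites()` →
`radial_profile()` / `fit_length_constant()` / `shape_metrics()` — and
`run_pipeline()` drives the whole chain from a YAML/list configuration.
Fitted objects have `tidy()`/`glance()` methods and result containers
have `autoplot()` methods.

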