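---
title: "Methods: multimodal optical characterization of different-age collagen matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal optical characterization of different-age collagen matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matrixage)
```

## The scientific problem

Type I collagen, the dominant structural protein of skin, tendon and bone,
accumulates non-enzymatic glycation cross-links (advanced glycation end
products, AGEs) over an organism's lifetime. These cross-links change how
purified collagen self-assembles into fibrils and, consequently, the optical
properties of the three-dimensional gels it forms. `matrixage` implements a
computational pipeline that characterizes such gels with four label-free
readouts — gelation turbidity kinetics, spatially-resolved diffuse
reflectance (DRS), confocal reflectance fiber morphometry (CRM), and
ATR-FTIR band ratios — together with a synthetic-data generator that encodes
three donor-age conditions (newborn, young-adult, old-adult rat tail-tendon
collagen) with known ground truth, so that every analysis stage can be
validated end to end.

## Age presets and the synthetic-data model

`age_presets()` fixes one parameter bundle per age. Published values are
used where they exist; the remainder are package defaults chosen inside
physiologically plausible ranges and **are not measurements**:

* **Kinetics.** Turbidity at 400 nm is `2.303 ×` absorbance (the base-10 to
  natural-log constant, used verbatim). Adult gels follow the logistic
  $\tau(t) = \tau_{max} / (1 + e^{-r(t - t_{1/2})})$ with
  $\tau_{max} = 0.67$ (young) and $0.38$ (old) — the two printed plateau
  values. The rates are defaults: young $r = 0.35\,\mathrm{min}^{-1}$,
  $t_{1/2} = 8$ min reproduces a ~3-min lag and a plateau by ~30 min; old
  $r = 0.8$, $t_{1/2} = 3$ gives an immediate exponential phase and a
  plateau by ~10 min. Newborn collagen polymerizes without reaching a
  plateau in 90 min; it is modelled as the saturating ramp
  $\tau(t) = 0.45\,t/(t+180)$, whose terminal slope
  ($1.1\times10^{-3}\,\mathrm{min}^{-1}$ at 90 min) stays above the
  plateau-detection cutoff.
* **Fluorescent AGEs.** Relative units; old-adult mean = 1.4 × young-adult
  (the published ~40% increase), newborn = young-adult (reported as not
  significantly different).
* **Scattering.** $\mu_s'(\lambda) = a\,(\lambda/550)^{-b}$ with
  $a = 1.2 / 0.8 / 0.4\ \mathrm{mm^{-1}}$ for young/newborn/old and
  $b = 1.2$: the published ordering (young > newborn > old across
  550–900 nm) inside a typical soft-gel range; the figures print no
  numbers.
* **Fibers.** Young-adult: 60 fibers, 18 µm long, 0.8 µm thick; newborn:
  25 × 30 µm × 1.4 µm; old-adult: 30 × 26 µm × 1.2 µm in a 512×512×41
  stack at 0.26 µm/pixel, 0.5 µm z-step — the "parabolic" pattern (young
  has the most but the thinnest/shortest fibers) without printed values.
* **FTIR bands.** Gaussians at 1032 and 1082 cm⁻¹ (σ = 10 cm⁻¹) and Amide
  I at 1656 (newborn) or 1632 cm⁻¹ (adults, σ = 12 cm⁻¹), on a weak linear
  baseline. Amplitude ratios I1032/I1082 = 0.90 / 0.95 / 1.30 for
  newborn/young/old. The old > young ordering encodes the carbohydrate
  band becoming predominant with age; newborn is placed close to
  young-adult because newborn AGE fluorescence equals young-adult's, and
  the band ratio is reported to correlate with fluorescence at r ≈ 0.99 —
  a newborn ratio far below young's would be inconsistent with that
  correlation (with these defaults the noiseless three-point Pearson r is
  0.993).

All generator randomness flows from one master seed through labelled
substreams (`split_seed()`), so adding or reordering calls never perturbs
other draws, and every dataset carries a `ground_truth()` bundle.

### What the generator does and does not emulate

It reproduces the statistical structure the analyses consume: sigmoid or
ramp kinetics with Gaussian noise, power-law scattering spectra pushed
through real photon transport, tubes with Gaussian cross-sections plus
speckle and detector noise, Gaussian IR bands on a smooth baseline. It does
**not** emulate fiber crossings or curvature (fibers are placed straight
and non-overlapping, since crossing fibers merge under skeleton-based
counting — a documented limitation), spatially varying background,
instrument drift, atmospheric water/CO₂ lines, or absolute fluorescence
calibration. Passing tests therefore demonstrate correctness of the
algorithms under the stated noise models, not robustness to every artifact
of real instruments.

## Photon Monte Carlo and the reflectance LUT

The forward model is weighted-photon Monte Carlo transport in a
homogeneous semi-infinite medium (the 1.5-ml gel in a 24-well plate is
treated as optically semi-infinite): exponential step sampling with
$\mu_t = \mu_a + \mu_s$, implicit capture (weight × albedo per
interaction), Henyey–Greenstein scattering with default $g = 0.9$ (typical
for collagenous tissue; $\mu_s = \mu_s'/(1-g)$), unpolarized Fresnel
boundary tests at the surface ($n_{medium} = 1.34$ hydrated gel /
$n_{above} = 1.0$), and Russian roulette below weight $10^{-4}$ with
survival probability 0.1. Two numerical choices matter:

* **Exact per-run energy conservation.** Roulette normally conserves energy
  only in expectation; here the weight created or destroyed by roulette is
  balanced against the absorbed tally, so `photon_tally()` sums to the
  launched weight to machine precision on every run while the estimator
  stays unbiased.
* **Finite simulation field.** Photons leaving a 15-mm sphere around the
  source are counted as lost. At the default detection radii (≤ 2.1 mm)
  this biases the ring signal by < 1% (measured against a 60-mm field)
  while bounding the walk length of near-unit-albedo photons, which would
  otherwise dominate run time at high $\mu_s'$.

Detection scores escaped weight into annular rings (default centers 1100,
1550, 2000 µm, width 200 µm — three distances in the 1100–2000 µm range;
the true probe's fiber layout is not public, so the geometry is declared,
not inferred). The simulation uses its own xoshiro256+ generator seeded
from the user seed: runs are bit-reproducible and independent of R's RNG
state.

**Validation.** The MC is checked against the closed-form diffusion dipole
with an extrapolated boundary and a partial-current escape function (the
fluence + flux combination with hemispheric Fresnel moments). This form
tracks the simulation to 5–7% over 2–8 mm at $\mu_s' = 1\,\mathrm{mm^{-1}}$,
$\mu_a = 0.01$; the simpler flux-only dipole deviates by up to ~18% at
these few-transport-mfp distances, which is a known shortcoming of that
approximation, not of the transport code (an independent analog Monte
Carlo agrees with the package's weighted MC to < 1%). Similarly, the
matched-$\mu_s'$ similarity relation (g = 0 vs g = 0.9) holds to 15% only
from about 4 transport mfp outward (~18% residual at 2 mfp); the tests
assert it in the diffusive regime.

The look-up table (`build_lut()`) runs the forward model on 50 log-spaced
$\mu_s'$ nodes over 0.1–5 mm⁻¹ at fixed $\mu_a = 0.001\,\mathrm{mm^{-1}}$
("close to zero" but positive, keeping the albedo < 1). Inversion
(`invert_mus_prime()`) minimizes the sum of squared log-reflectance
differences across rings, interpolating the table log-linearly in
$\mu_s'$, with node pre-scan plus golden-section refinement (tolerance
$10^{-4}\,\mathrm{mm^{-1}}$, ties toward the smaller value, boundary
estimates flagged). Log residuals equalize ring weighting across decades;
the objective is deliberately **not** invariant to rescaling all rings —
absolute calibration against the table matters, and a test asserts that a
×2 scaling changes the estimate. `fit_decay()` exposes the descriptive
exponential-decay constant $k$ of $\ln R = c - k\rho$ separately; the
inversion itself uses the ring values, since whether the original system
inverted $k$ or the raw rings is not stated.

## Fiber morphometry

Quantification runs on the 2D maximum-intensity projection (as the
published figure pipeline implies; 3D tracing is out of scope):

1. Gaussian pre-smoothing (σ = 1 px);
2. multiscale Hessian ridge enhancement at scales {1, 2, 4} px
   (scale-normalized magnitude of the most negative eigenvalue, maximum
   over scales, normalized to [0, 1] — hence invariance to intensity
   rescaling); a border band of twice the largest scale is blanked because
   smoothing padding manufactures edge ridges;
3. Otsu threshold, removal of objects < 30 px, plus two robustness gates:
   a hysteresis gate (components must contain at least one strong-response
   pixel, second-stage Otsu) and an absolute contrast gate (crest intensity
   ≥ median + 6 MAD of the smoothed image), so long weak noise-ridge
   chains and pure-noise images yield no fibers;
4. Guo–Hall thinning (chosen over Zhang–Suen, which deletes 2-px diagonal
   staircases entirely), pruning of spurs shorter than 10 px, and removal
   of free-standing skeleton fragments below the same length;
5. per-component measurement: length as geodesic pixel steps (1 axial,
   $\sqrt2$ diagonal, corner-cutting diagonals skipped) × pixel size;
   thickness as twice the mean distance-map value along the skeleton,
   where the distance map is computed on the *half-maximum intensity
   footprint* of each component (median crest intensity along the
   skeleton, threshold at half) rather than the detection mask — for a
   Gaussian cross-section the half-maximum footprint has exactly the
   nominal fiber width, while the detection mask width depends on the
   ridge filter.

On synthetic stacks with ≤ 30 non-overlapping fibers at SNR ≥ 5 this
recovers the count exactly, mean length within 10% and mean thickness
within max(10%, 1 pixel) — verified across ages, seeds and SNRs in the
test suite. Crossing fibers would merge into one component; the generator
therefore places fibers with clearance, and real crossing-rich networks
would need a different counting definition.

## FTIR band analysis

`preprocess_spectrum()` applies, in order: baseline subtraction (straight
line through the values at 1800 and 900 cm⁻¹, bracketing the analysis
region), offset correction (minimum over 1800–900 cm⁻¹ set to zero), and
vector normalization (unit Euclidean norm over the full grid). The anchors
and the ±8 cm⁻¹ peak windows are configuration, chosen to be inert on the
synthetic band model. `band_readout()` reports the Amide I position
(absorbance maximum in 1600–1700 cm⁻¹), I1032, I1082, the primary
glycation marker I1032/I1082, and secondarily I1032/I(Amide I). All
readouts are scale-invariant. `correlate_ratio_fluorescence()` is the
plain Pearson coefficient between per-age ratios and AGE fluorescence.
Atmospheric correction is out of scope (it needs measured vapor spectra);
synthetic spectra contain no vapor lines.

## Kinetics fitting

`fit_logistic()` fits the three-parameter logistic by Levenberg–Marquardt
with data-driven initialization ($\hat\tau_{max} = \max\tau$, $t_{1/2}$ at
the half-max crossing, $r = 4\,\max\mathrm{slope}/\hat\tau_{max}$) and a
fixed grid of five jittered restarts (deterministic, no RNG state
touched). The descriptive phase boundaries are made operational as: lag =
first time τ ≥ 10% of the fitted plateau; time-to-plateau = first time
τ ≥ 95%; plateau reached iff the mean slope over the final 10 min is
< 0.001 min⁻¹ *and* the 95% crossing occurs within the record. These
cutoffs reproduce the published phase structure on the presets (young: lag
≤ 3 min, plateau ≤ 30 min; old: lag ≤ 1 min, plateau ≤ 10 min; newborn:
no plateau). Because "maximal turbidity" could mean either the fitted
asymptote or the last observation, `glance()` reports both (`tau_max` and
`final_turbidity`).

## Pipeline, reproducibility and problem sizes

`run_all()` executes generate → analyze → report for all requested ages
from one `run_config()`; every artifact embeds the config's md5 digest,
and identical config + seed reproduce a byte-identical consolidated JSON
report. The default configuration uses a 30-node LUT at 2×10⁴ photons per
node, 5×10⁴ photons per forward wavelength at four wavelengths, and full
preset fiber counts in a 512×512×41 stack — about a minute of computation —
while the validation suite uses a 50-node, 10⁵-photons-per-node table and
10⁶-photon forward runs for the physics checks. These sizes were chosen so
that Monte Carlo noise sits well below every tolerance being asserted
(ring-level noise ≲ 1% at 10⁶ photons against 10% bands).

## Known limitations

* The semi-infinite medium ignores finite gel depth and well walls;
  wavelength enters only through $\mu_s'(\lambda)$ (no chromatic boundary
  effects).
* Joint ($\mu_a$, $\mu_s'$) inversion is out of scope; absorption is fixed
  near zero as in the original measurement protocol, so absorbing samples
  would bias $\mu_s'$.
* Morphometry is 2D-projection based; fibers steeply inclined in z are
  foreshortened, and crossings merge.
* Generator defaults for unpublished quantities (rates, amplitudes, fiber
  statistics) are stand-ins: cross-age *orderings* and printed values are
  meaningful test targets, absolute synthetic values are not.
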