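# matrixage

Multimodal optical characterization of type I collagen 3D matrices as a
function of donor age.

Collagen extracted from donors of different ages (newborn, young-adult,
old-adult rats in the reference system) assembles into gels with measurably
different optical properties, driven largely by the age-dependent
accumulation of advanced glycation end products (AGEs). `matrixage`
implements the full computational side of a label-free characterization
pipeline for such gels:

* **Gelation kinetics** — conversion of 400-nm absorbance records to
  turbidity (τ = 2.303 · A) and least-squares fitting of the logistic
  fibrillogenesis model τ(t) = τ_max / (1 + e^{−r(t − t_half)}) with
  operational lag / exponential / plateau phase descriptors.
* **Diffuse reflectance spectroscopy (DRS)** — a weighted-photon Monte
  Carlo forward model of spatially-resolved reflectance R(ρ, λ) for a
  homogeneous semi-infinite gel (Henyey–Greenstein scattering, Fresnel
  boundaries, Russian roulette with exact per-run energy conservation),
  validated against the diffusion-dipole closed form, plus look-up-table
  inversion of multi-distance measurements into reduced scattering spectra
  μs′(λ) with absorption fixed near zero.
* **Confocal reflectance morphometry (CRM)** — maximum-intensity
  projection, multiscale Hessian ridge segmentation, Guo–Hall
  skeletonization and distance-map measurement of fiber number, length and
  thickness from 3D image stacks.
* **ATR-FTIR band analysis** — baseline/offset/vector-normalization
  preprocessing, Amide I peak position (1656 cm⁻¹ newborn vs 1632 cm⁻¹
  adult collagen), the I1032/I1082 carbohydrate glycation marker, and its
  Pearson correlation with AGE fluorescence.
* **Synthetic data with ground truth** — three age presets encoding the
  published contrasts (plateau turbidities 0.67 vs 0.38; +40% AGE
  fluorescence in old age; μs′ ordering young > newborn > old; the
  parabolic fiber-statistics pattern; the Amide I shift) generate inputs
  for every stage, so the whole pipeline is testable end to end.

Functions are tibble-in / tibble-out and pipe-friendly; fitted objects
support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Fit the gelation kinetics of a synthetic old-adult curve and read out its
FTIR glycation markers:

```r
library(matrixage)

curve <- age_preset("old_adult") |>
  generate_kinetics(noise_sd = 0.01, seed = 1)
fit <- fit_logistic(curve)
fit
#> Logistic gelation kinetics fit
#>   tau_max  0.3815   rate 0.7279 min^-1   t_half 3.12 min
#>   lag 1 min   plateau at 8 min   final turbidity 0.3907

bands <- age_preset("old_adult") |>
  generate_ftir_spectrum(noise_sd = 0) |>
  preprocess_spectrum() |>
  band_readout()
bands
#> # A tibble: 1 × 5
#>   amide_I_position I_1032 I_1082 ratio ratio_amide
#>              <dbl>  <dbl>  <dbl> <dbl>       <dbl>
#> 1             1632  0.109 0.0839  1.30       0.390
```

The fitted plateau (0.38) matches the old-adult preset, the fit detects the
published fast-gelation pattern (lag ≤ 1 min, plateau by ~10 min), the
Amide I peak sits at the adult position 1632 cm⁻¹, and the carbohydrate
ratio 1.30 is the old-adult glycation level.

The whole multimodal pipeline — LUT construction, forward simulation,
inversion, morphometry, band analysis and the cross-age report — runs from
one configuration:

```r
report <- run_all(run_config(seed = 3))
report$cross_age
#> $mus_prime_ordering            # young > newborn > old at every wavelength
#> [1] TRUE
#> $fiber_count_ordering          # young-adult has the most fibers
#> [1] TRUE
#> $carbohydrate_ratio_ordering   # I1032/I1082: old > young
#> [1] TRUE
#> $ratio_fluorescence_r
#> [1] 0.9933992
```

A thin command-line interface over the same functions lives at
`inst/cli/matrixage.R`
(`generate`, `simulate-drs`, `build-lut`, `invert`, `fit-kinetics`,
`analyze-stack`, `analyze-ftir`, `run-all`).

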