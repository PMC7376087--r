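# flickspec

Membrane mechanics from contour flicker, membrane structure from FTIR — in
one tested R package.

## What it measures, and for whom

Lipid bilayers and cell membranes undulate under thermal agitation. For a
quasispherical giant unilamellar vesicle (GUV) or a red blood cell (RBC)
imaged at its equator, the statistics of the contour's radial fluctuations
encode the membrane's elastic constants. `flickspec` is for membrane
biophysicists who film such objects (or analyze pre-extracted contours) and
want bending moduli, tensions and — for RBCs — membrane-skeleton
confinement strengths, plus the companion FTIR analysis used to
characterize bilayer structure: melting curves, transition temperatures, a
thermal-expansivity proxy, and probe-partitioning fractions.

Every stage is testable without instrument data: a synthetic module
generates contour sequences, rendered video frames and infrared spectra
with exactly the statistical structure the estimators assume.

## The models at the core

Each contour is a Fourier series around its center,
`r(θ) = R (1 + Σₙ [aₙ cos nθ + bₙ sin nθ])`, and the spectrum of
mean-squared amplitudes `⟨δₙ²⟩ = Var(aₙ) + Var(bₙ)` is fitted with
planar-membrane models:

- tension + bending:
  `⟨δₙ²⟩ = (1/2π) (1/κ̃σ̃) [1/n − (2σ̃ + n²)^(−1/2)]`,
  with `κ̃ = κ/kBT` and `σ̃ = σ⟨R⟩²/2κ`;
- high-mode (bending-only) limit: `⟨δₙ²⟩ ≈ n⁻³/(2πκ̃)`, fitted over
  modes n = 5–18 to read off the bending modulus;
- RBC confinement: with `s = √(σ̃² − γ̃)` and `γ̃ = γ⟨R⟩⁴/κ`,
  `⟨δₙ²⟩ = (1/2πκ̃s) [(σ̃ + n² − s)^(−1/2) − (σ̃ + n² + s)^(−1/2)]`,
  evaluated on the principal complex branch when `γ̃ > σ̃²`.

The FTIR chain tracks the CH₂ symmetric stretch (~2850 cm⁻¹) against
temperature, takes the main transition temperature `Tm` from the maximum of
the smoothed first derivative of the melting curve, computes
`β = (∂νs/∂T)/νs`, and decomposes the C≡O band of membrane-solubilized
W(CO)₆ (1960–1990 cm⁻¹) into components at 1981/1975 cm⁻¹ with core area
fraction `f1 = I(νas1)/(I(νas1) + I(νas2))`.

## Worked example

Simulate a vesicle with bending modulus 44 kBT under weak tension, build
its fluctuation spectrum from 2000 frames, and fit the high modes:

```r
library(flickspec)

p  <- spectrum_params(kappa_tilde = 44, sigma_tilde = 0.01, mean_radius = 50)
ms <- sample_contour_modes(p, model = "tension", n_frames = 2000, seed = 1)
sp <- estimate_spectrum(ms)
sp
#> Fluctuation spectrum: modes 2..18, 2000 frames, <R> = 50.000
#>   n       delta2           se frames mean_radius
#> 1 2 4.563724e-04 1.443176e-05   2000          50
#> 2 3 1.391059e-04 4.398916e-06   2000          50
#> 3 4 5.547513e-05 1.754278e-06   2000          50
#> 4 5 2.954322e-05 9.342386e-07   2000          50
#> 5 6 1.684181e-05 5.325847e-07   2000          50
#>   ... 12 more modes

fit_bending_free(sp)
#> Membrane spectrum fit (free model), modes 5..18
#>   kappa_tilde        43.9 +/- 0.242
#>   reduced chi-squared: 0.426
```

The fitted modulus (43.9 ± 0.24 kBT) recovers the generating 44 kBT within
its statistical error; `delta2` falls roughly as `n⁻³`, and the standard
errors are the Gaussian-theory `⟨δₙ²⟩·√(2/N)`. The same spectrum object
feeds `fit_tension_model()` (adds `σ̃`) or, for RBC data,
`fit_confined_model()` (adds `γ̃`). Image stacks go through
`track_sequence()`/`run_flicker()` first.

On the FTIR side:

```r
mc <- generate_melting_curve(tm = 27, width = 3, noise_sd = 0.05, seed = 7)
estimate_tm(mc)
#> [1] 27.03242

fit_two_gaussians(generate_co_band(areas = c(3, 1)))
#> Two-Gaussian carbonyl band decomposition
#>   component 1 (core):       center 1981.00 cm^-1, sigma 1.50, area 3
#>   component 2 (interface):  center 1975.00 cm^-1, sigma 3.00, area 1
#>   f1 (core area fraction):  0.7500
```

The transition midpoint is recovered within 0.04 °C despite position noise,
and the band decomposition returns the generating areas, hence
`f1 = 3/(3+1) = 0.75`: the fraction of probe buried in the hydrophobic
core.

## Documentation

The methods vignette (`vignettes/flicker-and-ftir-methods.Rmd`) documents
the models and their assumptions, the numerical choices (cancellation
guards, complex-branch evaluation, matched-filter contour detection,
scale-adaptive derivative-peak refinement), what the synthetic generators
do and do not emulate, and known limitations.
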