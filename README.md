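# quicsr

Quality metrics for single-channel fluorescence microscopy images —
confocal or super-resolution (STED) — computed from the spatial
autocorrelation function of a single image. `quicsr` is an R
implementation of the QuICS (Quality assessment by Image Correlation
Spectroscopy) approach, aimed at microscopists who want an unbiased,
whole-image alternative to hand-picked line-profile FWHM measurements when
tuning acquisition settings (depletion power, line averaging,
photobleaching trade-offs).

## The model

For an image *I(x, y)* the normalized 2D autocorrelation is

    G(δx, δy) = ⟨I(x, y) I(x + δx, y + δy)⟩ / ⟨I⟩² − 1

with averages restricted to an optional region-of-interest mask (e.g. the
nucleus). The surface is collapsed to a radial profile *G(ρ)* by angular
averaging. If the sample is a random field of particles imaged through a
Gaussian point spread function of 1/e² waist *w*<sub>PSF</sub>, the
noise-free part of *G(ρ)* is a Gaussian,

    G_NF(ρ) = G_NF(0) · exp(−ρ² / w²) + G_NF(∞),

while uncorrelated pixel noise contributes only at ρ = 0. Fitting this model
either **skipping the zero lag** (ρ<sub>min</sub> = 1 px) or fitting the
**cross-correlation of two noise-independent half-images** obtained by
checkerboard downsampling (ρ<sub>min</sub> = 0) yields three parameters:

| metric | definition | meaning |
|---|---|---|
| Resolution | R = √(2 ln 2) · w | FWHM of the effective PSF, in nm; features of finite size can only increase it |
| Brightness | B = G_NF(0) · I_av = σ²ₚ / I_av | particle contrast in counts, diluted by uniform background |
| Noise | N = (G(0) − G_NF(0)) / G_NF(0) = σ²noise / σ²ₚ | 0 = noiseless, 1 = noise fluctuations equal particle fluctuations |

When the fitted offset G_NF(∞) is nonzero the raw zero lag is
offset-corrected before forming N, so numerator and denominator share a
baseline (identical to the plain formula at zero offset).

## Worked example

```r
library(quicsr)

# a synthetic STED-like frame with known ground truth:
# 256x256 px at 20 nm/px, 100 point emitters, PSF FWHM 240 nm,
# 1e4 photons/particle, uniform background, Poisson noise
sim <- simulate_image(shape = c(256, 256), pixel_size = 20,
                      n_particles = 100, psf_fwhm = 240,
                      photons_per_particle = 1e4, background_level = 1.5,
                      noise_model = "poisson", seed = 2)
res <- quics_analyze(sim$image)
print(res)
#> <quics_result> 'synthetic' (skip_zero)
#>   Resolution R : 235.1 nm
#>   Brightness B : 28.82 counts
#>   Noise N      : 0.02804
#>   I_av 16.28, raw G(0) 1.7723, w 9.983 px, rho [1, 30]
```

The recovered resolution (235 nm) matches the generator's 240 nm PSF FWHM;
the brightness is the particle variance over the mean (the generator's
ground truth here is 28.0 counts), and N ≈ 0.03 reflects the small Poisson
noise variance relative to the particle-induced variance.

Real images enter through `read_image("cell.tif", pixel_size = 20)` with an
optional `read_mask("cell_mask.png")`, and `run_batch()` analyzes many
images and reports mean ± SEM per metric. `photobleaching()` converts a
series of frame means into percentage intensity loss. A thin command-line
wrapper lives at `inst/cli/quics.R` with verbs `analyze`, `batch`,
`simulate` and `bleach`.

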