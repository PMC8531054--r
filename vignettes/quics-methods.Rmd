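---
title: "Correlation-based image quality metrics: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-based image quality metrics: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quicsr)
```

## The statistical model

`quicsr` treats a fluorescence image as a realization of a stationary
random field: particles (molecular clusters, replication foci, vesicles)
at random positions, convolved with the point spread function (PSF) of the
microscope, on top of a uniform background, corrupted by pixel noise. The
normalized spatial autocorrelation function (ACF)

$$G(\delta_x,\delta_y) \;=\;
\frac{\langle I(x,y)\, I(x+\delta_x, y+\delta_y)\rangle}
     {\langle I\rangle^2} - 1$$

then separates the three ingredients by where they live in lag space:

* the **particle + PSF** term is a smooth, approximately Gaussian peak
  whose 1/e² width $w$ (in pixels) is set by the effective PSF and the
  particle size,
* **uncorrelated pixel noise** (shot noise, read noise) contributes only
  to the zero-lag point, because it is independent between pixels,
* a **uniform background** contributes nothing to the covariance but
  inflates $\langle I\rangle$, scaling $G$ down.

Fitting the Gaussian model
$G_{NF}(\rho) = G_{NF}(0)\, e^{-\rho^2/w^2} + G_{NF}(\infty)$
to the angle-averaged profile $G(\rho)$ gives the three quality metrics:
$R = \sqrt{2\ln 2}\,w$ (the FWHM of the effective PSF, reported in nm),
$B = G_{NF}(0) I_{av} = \sigma_p^2 / I_{av}$ (particle contrast in
counts), and $N = (G(0) - G_{NF}(0))/G_{NF}(0) = \sigma^2_{noise} /
\sigma^2_p$. Even when the true PSF is not Gaussian, the Gaussian fit is a
serviceable approximation for extracting $R$.

Two estimators of the noise-free amplitude are provided and should agree
on well-behaved data (`method` argument of `quics_analyze()`):

* `skip_zero` — fit $G(\rho)$ with $\rho_{min} = 1$ pixel, excluding the
  only point the noise touches;
* `downsample_cc` — split the image into two half-images drawing on
  disjoint checkerboard parity classes of pixels (so their noise is
  independent), cross-correlate them, and fit from $\rho_{min} = 0$.

## Numerical and design choices

**Boundary handling.** An FFT evaluates the correlation numerator as a
*cyclic* product, which silently pairs opposite image edges. The default
`boundary = "padded"` zero-pads image and mask to twice their size and
normalizes every lag by its count of valid in-mask pixel pairs (the mask's
own autocorrelation), so no wrap-around pair is ever counted and a masked
region embedded in a larger canvas yields the identical ACF. `"circular"`
retains the plain cyclic definition; the two differ only at lags that are
large relative to the field, and both are validated against a direct
$O(N^4)$ double-loop oracle to $10^{-10}$ in the test suite.

**Mask semantics.** Both the numerator average and $I_{av}$ run over
in-mask pixels only; under padding, per-lag pair counts come from the
mask correlation. Lags with no valid pair are reported absent (`NA`).

**Radial binning.** Each lag cell joins bin
$\mathrm{round}(\sqrt{\delta_x^2+\delta_y^2})$ (bin width 1 px) and bins
are unweighted means of their cells; bin 0 is exactly the zero-lag cell.
This is the simplest reading of an angular mean on a square grid; per-bin
cell counts are carried along and can weight the fit
(`weight_by_npairs = TRUE`), though the default fit is unweighted.

**Checkerboard split.** Within every 2×2 block, the two diagonal pixels
(even parity $i+j$) average into one pixel of the first half-image and the
two anti-diagonal pixels (odd parity) into the second, so each half-image
is parity-pure and the two draw on disjoint pixel sets. Halves are
resampled back to full size by 2×2 replication — nearest-neighbour on
purpose, since interpolation would re-mix the parity classes and
reintroduce noise correlation. Odd trailing rows/columns are cropped with
a warning. The pairing averages each base pixel with its diagonal
neighbour inside the block; this keeps both half-size grids complete
without inventing data at the image border.

**Fitting range.** $\rho_{min}$ is 1 px for `skip_zero`, 0 for
`downsample_cc`. The upper bound replaces a by-eye choice with an
iterative rule (`auto_fit_range()`): fit over the available range, set
$\rho_{max} = \max(8, \mathrm{round}(3\hat w))$ — three widths cover
>99.98 % of the Gaussian, i.e. "a single Gaussian component" — capped at
one quarter of the smaller image dimension, refit, and stop when the bound
moves at most one bin (10 rounds maximum, then the cap with a warning). A
`fixed` policy via `fit_range()` accepts user bounds.

**Fitting.** Levenberg–Marquardt (`minpack.lm::nlsLM`) with bounds
(amplitude ≥ 0, $w \in (0.1, 2\cdot\mathrm{cap}]$, offset free); when LM
fails to assemble a model object (a known failure mode at near-perfect
fits), a bounded `nls(algorithm = "port")` retry covers it. Initial
guesses: offset from the median of the tail quartile, amplitude from the
first fitted bin above it, width from the $1/e^2$ crossing. The fitter is
deterministic. A converged fit whose amplitude is within two standard
errors of zero is flagged, and any flag voids the headline metrics into
`NA` rather than reporting silently.

**Offset in $N$.** A nonzero fitted offset models large-scale structure
that is neither particle signal nor pixel noise, so the raw zero lag is
offset-corrected before normalizing:
$N = (G(0) - G_{NF}(\infty) - G_{NF}(0))/G_{NF}(0)$. With zero offset this
is exactly the plain definition. Estimation error can push $N$ slightly
negative; values in $[-0.05, 0)$ are clamped to 0 with a warning, lower
values are flagged as suspect.

**Units.** $R$ is reported in nm ($w$ in pixels × pixel size); $B$ in raw
intensity counts — comparable only across identical acquisition settings,
since it folds in excitation level, detector gain and dwell time; $N$ is
dimensionless.

## The synthetic generator

`simulate_image()` emulates exactly the statistical structure the metrics
assume: a Poisson-or-fixed number of emitters placed uniformly at
sub-pixel positions, each rendered as a 2D Gaussian of total flux
`photons_per_particle` and waist $\sqrt{w_{PSF}^2 + w_p^2}$ (Gaussian
convolution closure — a finite particle waist adds to the PSF in
quadrature, so the generator's `true_R` is
$\sqrt{\mathrm{FWHM}_{PSF}^2 + (\sqrt{2\ln2}\, w_p)^2}$), plus a uniform
background, then Poisson and/or Gaussian noise. Defaults are the
package's standard study conditions: 256×256 px at 20 nm/px, 100
particles, PSF FWHM 240 nm, $10^4$ photons per particle — a sparse,
high-signal STED-like field. Ground truth is computed from the rendered
noiseless frame: $\sigma_p^2$ is its population variance (edge-truncated
flux included), and $\sigma^2_{noise}$ is analytic (the mean for Poisson
at unit gain, $\sigma^2$ for Gaussian, their sum for both).
Particles are rendered by evaluating the Gaussian at pixel centers, not by
area integration; at the enforced sampling (`psf_fwhm >= 2 * pixel_size`)
the width bias is below 1 %. One seeded generator drives placement, then
noise, in that fixed order, so frames are bit-reproducible.
`simulate_bleach_series()` freezes the particle positions and scales the
expected flux by `bleach_survival^k` per frame with independent noise.

What the generator does **not** emulate: realistic (vectorial, doughnut)
STED PSFs, clustered or structured particle placement, detector
afterpulsing or correlated read noise, drift, or sample autofluorescence
gradients. Passing tests therefore demonstrate correctness of the
estimators *under the model's own assumptions*; on real images, deviations
(structured background, non-uniform nuclei) are exactly what the ROI mask
and fitted offset are there to absorb, and residual model mismatch shows
up as a flagged fit or an inflated offset rather than a silent number.

## Problem sizes and tolerances in the tests

The suite validates the FFT path against a brute-force direct-space oracle
on fields up to 24×24 (the oracle is $O(N^4)$), and runs all
pipeline-level recovery checks at the standard 256² scenario with 4–10
seeded replicates per condition: resolution recovery within 5 % of truth
across PSF FWHM ∈ {160, 200, 240} nm, the finite-particle quadrature
closure within 5 %, brightness gain scaling to $10^{-6}$ and background
dilution within 10 %, the noise calibration curve within 20 % over
variance ratios {0.25, 1, 4}, and agreement of the two noise-free
estimators within 10 % on $R$ and 15 % on $B$. Smaller 96²–128² fields are
used where only contracts (serialization, batch orchestration) are under
test; at those sizes the per-seed spread of $R$ is noticeably larger
because fewer independent correlation speckles fit in the field.

## Known limitations

* $B$ is instrument-bound; comparisons across acquisition settings are
  meaningless without calibration.
* The Gaussian ACF model is single-component; images whose correlation
  shows two clearly separated scales should be fitted with a `fixed`
  range bracketing the narrow component (the auto rule does this for
  moderately separated scales, as exercised in the tests).
* Temporal correlation (diffusion, flow) and multi-channel
  cross-correlation are out of scope; the analysis is strictly static and
  single-channel.
* Circular-boundary ACFs of masked, off-center regions include
  wrap-around pairs by construction; use the default padded boundary for
  masked data.
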