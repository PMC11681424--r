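---
title: "Dye-amount unmixing for Papanicolaou cytology: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dye-amount unmixing for Papanicolaou cytology: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(papunmix)
```

## The physical model

A stained, transparent specimen attenuates transmitted light
multiplicatively. Under the Lambert–Beer law the absorbance at wavelength
$\lambda$ is additive over dyes,
$\alpha(\lambda) = \sum_i c_i\,\varepsilon_i(\lambda)$, with $c_i$ the
(relative) amount of dye $i$ and $\varepsilon_i$ its spectral absorption
coefficient, and the transmitted intensity is
$I_1(\lambda) = 10^{-\alpha(\lambda)} I_0(\lambda)$. Base-10 attenuation is
used throughout; all "absorbance" in this package is decadic optical
density.

A multispectral camera integrates $I_1$ against each band's sensitivity.
We adopt the standard narrowband approximation — each channel samples the
spectrum at its center wavelength — so per pixel and band
$\alpha_k = \log_{10}(g_{0k}/g_k)$, where $g_k$ is the measured count and
$g_{0k}$ the white (glass) reference. Stacking bands gives the linear
mixing model $a = Hc$ with the $N\times M$ stain matrix $H$ whose columns
are the per-band $\varepsilon_i$. With $M < N$ and full column rank, the
least-squares amount estimate is the Moore–Penrose solution $c = H^+a$,
computed here by SVD with singular values below
$\sqrt{\varepsilon_{\mathrm{mach}}}\,\sigma_1$ treated as zero. The
narrowband approximation's error is a known property of real filter
wheels; it is accepted, not modelled.

Assumptions worth stating: pixel value linear in intensity (no gamma in
the raw data); a single focal layer, so amounts integrate the dye within
the depth of field; dyes mix additively in absorbance (overlapping stained
objects add their amounts).

## Calibration from single-stain specimens

A specimen stained with one dye has $a = \beta\,\varepsilon_l$ at every
pixel, $\beta$ the local abundance. `estimate_stain_vector()` normalizes
each sampled pixel spectrum to unit Euclidean norm (removing $\beta$),
averages the unit vectors, and renormalizes. A printed form of this
estimator elsewhere divides by the *squared* norm, which weights each
pixel by $1/\beta$; since the published spectra are unit-scale curves and
the estimate is a direction, we chose the unit-norm (direction-mean)
form. Both are invariant to per-pixel positive scaling — the property the
tests pin down — and differ only in how noise is weighted across pixels.

Calibration areas are designated manually (rectangles or mask files);
fewer than 25 pixels (a 5×5 sample) triggers a warning, mirroring typical
practice of averaging a few dozen absorbances per image. Column
conditioning is checked when the matrix is assembled; near-collinear dye
pairs are named in the error because an ill-conditioned $H$ silently
amplifies noise in $H^+$.

## Normalization and background elimination

Unmixed amounts are relative (each $\varepsilon_l$ has unit norm, so $c_l$
carries the specimen's staining scale). For interpretability each dye
plane is divided by a reference value $Q_l$: the 99th percentile of that
dye's amounts over a designated well-stained region, putting well-stained
tissue near 1. The reference values published with the original clinical
calibration ($Q_{EY} = 2.003$, $Q_H = 1.889$, $Q_{LG} = 2.550$,
$Q_{OG} = 1.213$) ship as a preset; they are only meaningful together with
that study's measured stain matrix, so new acquisitions should call
`compute_reference_values()`.

Real slide background retains a slight residual stain. A pixel is treated
as background iff *every* dye amount is below its threshold $T_l$, taken
as the 99th percentile (configurable) of amounts inside a user-selected
glass region. Two consequences of this rule are deliberate:

* Raising any $T_l$ can only grow the background set (monotonicity).
* With four dyes at the 99th percentile, up to $\approx 4\%$ of true glass
  pixels remain "stained" (union bound); a higher percentile tightens
  this. The default favors keeping faintly stained tissue over perfectly
  cleaning glass.

Thresholds are applied to whichever scale they were derived on; because
normalization is a per-dye positive scaling, masking commutes with it
(thresholds divide by the same $Q_l$), a property the tests verify.

## Patch categorization and cluster summary

Dye maps are tiled into 10×10-pixel patches anchored at the image origin;
right/bottom remainders are discarded. Per patch:

1. **nucleus** if strictly more than 50% of pixels are H-stained
   ($c_H \ge T_H$) — 50 of 100 is *not* a nucleus;
2. else **background** if non-stained pixels (all dyes below threshold)
   exceed $b\%$;
3. else **mucin** (cytoplasm).

The nucleus test precedes the background test. $b$ must be tuned per image
set; the default is 90, chosen so that only patches almost entirely on
glass are dropped. There is no separate "H-stained" cut-off; the
background threshold $T_H$ doubles as the stain criterion, the simplest
rule consistent with the masking logic.

Patch features are the mean amounts over *stained* pixels only (the area
where any dye exists), so a patch half on glass is characterized by its
tissue half. The cluster-level summary is the **LEGH ratio**: LEGH-classified
mucin patches over all mucin patches, nuclei and background excluded.

## Fisher discriminants and the orientation of the bundled presets

`fit_fisher()` is the classical two-class Fisher discriminant:
$w \propto S_W^{-1}(\mu_{LEGH} - \mu_{EC})$ with pooled within-class
scatter $S_W$ (ridge-regularized with a warning when singular), and the
equal-prior midpoint intercept $b = -w\cdot(\mu_{EC}+\mu_{LEGH})/2$ — the
published decision functions carry an intercept, so the model is affine.
Ties ($D = 0$) go to the positive side.

Three fixed discriminants trained on clinical mucin patches ship as
presets (2D over (EY, OG); 3D over (EY, LG, OG); an sRGB baseline). Their
published description says "$D \ge 0$ is LEGH", but that reading is
irreconcilable with the published evaluation: any OG-free EC sample has
$D_{2D} = 15.01\,EY + 1.454 > 0$, yet the published confusion table
reports 49/49 EC test samples predicted EC; likewise the weight vectors
point toward the EY-rich/OG-free side, and LEGH mucin is the *more-OG,
less-EY* class. The positive side of the printed coefficients is
therefore the EC class. Orientation is consequently an explicit model
field (`positive_label`): presets default to `"EC"` (reproducing the
published tables and the dye chemistry), and
`preset_discriminants(positive_label = "LEGH")` yields the literal
printed sentence for anyone who wants it. The published
precision/recall columns are likewise inconsistent across methods under
any single positive-class convention, so `evaluate_classification()`
requires `positive_class` explicitly; accuracy and F are
convention-consistent.

## sRGB rendering

The render exists for visual QC, not colorimetry (the imaging-system study
this follows judged its own render "acceptable" rather than accurate).
Per-band transmittance $g_k/g_{0k}$ is linearly interpolated onto a 5-nm
grid over 380–780 nm (constant beyond the outer bands), integrated
against a daylight illuminant and the CIE 1931 2° color matching
functions, mapped through the standard D65 XYZ→sRGB matrix,
white-balanced in linear RGB so a fully transmitting pixel is exactly
white, and gamma-encoded. Two implementation choices:

* CMFs use the Wyman–Sloan–Shirley piecewise-Gaussian analytic fits
  (≈1% of peak) rather than an embedded table.
* The illuminant is a Planckian radiator at 6504 K, the correlated color
  temperature of D65; the residual chromaticity difference is absorbed by
  the glass white balance, which also makes the render invariant to
  common exposure scaling.

sRGB patch features for the baseline discriminant are means of the
gamma-encoded channels in $[0,1]$ — the published coefficient magnitudes
(≈ 83–369) are consistent with unit-range inputs, though the original
scale is unstated; this choice is recorded here because it affects where
the sRGB preset's boundary falls on re-rendered data.

## The synthetic phantom generator

Phantoms provide ground truth where clinical MS images are unavailable.
A scene is a list of elliptical cells (H-stained nucleus over
counterstained cytoplasm) on glass carrying a small residual stain
(default amount 0.01 per dye), rendered through the forward model with
Poisson shot noise at a stated photon count per band (default $10^4$ at
the white level) and uniform quantization (default 12-bit). Noise
parameters are not published for the original instrument; these defaults
represent a mid-range scientific CMOS acquisition. Seeds are mandatory
and the generator restores the caller's RNG state.

Default dye spectra are Gaussian-shaped curves with the qualitative
features of the measured ones: H broad around 575 nm, EY sharp near
520 nm, LG absorbing in the red (≈630 nm) and very low at 480–540 nm, OG
absorbing near 480 nm and negligible beyond 530 nm; unit-normalized, with
a finite condition number (≈3.1 on the 14-band grid).

The two-class feature generator draws per-patch mean amounts around class
means emulating the clinical contrast — EC: EY-rich (0.55) and OG-free
(0.01); LEGH: OG-rich (0.35) with reduced EY (0.25); H ≈ 0.02 in both —
with common spread 0.08, truncated at zero. The ≈4–5σ mean separation
expresses the reported strong significance of the EY and OG differences.

What phantoms do **not** emulate: real cell morphology and chromatin
texture, co-staining of nuclei by counterstains, stain-matrix measurement
error (the same spectra generate and unmix, except where tests perturb
them), focus/thickness variation, and spatial noise correlation. Passing
phantom tests therefore validates the algebra, the noise behavior and the
decision logic — not clinical performance.

## Numerical and degenerate-input choices

* Counts are clipped below at `floor` (default 1 count) before the log, so
  zero/saturated-dark pixels give large finite absorbance instead of Inf.
* Pixels brighter than glass (shot noise) yield negative absorbance; it is
  kept and absorbed by least squares rather than clipped, to avoid biasing
  faint amounts upward.
* Negative unmixed amounts are clipped to zero *after* solving (default
  on), since all masking/patch logic assumes nonnegative amounts; the
  solution itself is never constrained.
* Wavelength mismatch between absorbance and stain matrix warns and
  proceeds by band order; band-count mismatch is an error.
* All rectangle/mask coordinates are 0-based, row-major, half-open.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
phantoms of 20–80 px square (up to 64 patches), 100-pixel calibration
strips, 20 random unmixing instances per oracle comparison, three seeds
per photon-count level, and 100 samples per class for the discriminant
experiments. These sizes give stable statistics for the assertions made
while keeping the full suite in the order of seconds.

## Known limitations

* Stain matrices must come from single-stain specimens; blind estimation
  is out of scope.
* The bundled reference values and discriminants transfer only to data
  acquired and calibrated like the original clinical study.
* Single focal plane; no z-stack or extended-focus handling.
* The bismarck brown (BY) dye is excluded, as in the clinical calibration
  this follows (its single-stain signal is too weak to matter for mucin).
* The sRGB path is not color-managed.
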