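---
title: "Quantifying edge sharpness in paired MRI reconstructions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying edge sharpness in paired MRI reconstructions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbitsharp)
```

## The measurement problem

Accelerated MRI with deep-learning reconstruction (DLR) tends to look
*sharper* than a conventional reconstruction (CR) of the same anatomy:
boundaries such as optic nerve margins and extraocular muscle edges appear
crisper, while noise is suppressed. Readers notice this, but Likert ratings
alone cannot say *what* changed. orbitsharp quantifies the boundary itself:
how fast intensity rises across an edge (steepness), over how many pixels
it rises (10--90% edge width) and by how much (edge contrast), alongside
the general-purpose image-quality metrics (SSIM, MS-SSIM, SNR, PSNR, blur
percentage, a perceptual blur metric, and a perceptual sharpness index) and
the agreement statistics used to summarize a paired reading study.

All operations consume a `gray_image`: a 2D matrix of intensities
min--max normalized to [0, 1]. Whether normalization should be per-image or
per-sequence is an open choice for multi-image studies; the package
normalizes per image (it makes steepness and contrast comparable across
images of different dynamic range) and carries the choice in the object so
downstream reports can flag it.

## The edge measurement chain

**Gradient.** `compute_gradient()` uses interior central differences
`(I[i+1] - I[i-1]) / 2` with one-sided differences at the borders, and the
Euclidean magnitude `sqrt(gx^2 + gy^2)`. The magnitude is rotationally
invariant up to grid effects, which is why it, and not a directional
derivative, underlies steepness.

**Edge selection.** `detect_edges()` supports the three classical
detectors (Roberts 2x2, Sobel 3x3, Canny with Gaussian presmoothing,
non-maximum suppression and hysteresis). Detectors only *select* pixels;
every feature below is computed from the image and its central-difference
gradient, never from the detector's internal response. Three numerical
choices matter, all overridable:

* *Automatic thresholds* are Otsu splits of the nonzero gradient
  magnitudes, computed on the thinned (non-maximum suppressed) candidate
  set. Off-ridge pixels outnumber ridge pixels by two orders of magnitude
  in noisy images and would otherwise swamp the histogram. When the
  candidate magnitudes are near-uniform (relative spread < 20% of the
  maximum) there is only one class and no split is attempted — this is the
  situation on a clean image containing a single edge strength.
* *Small components are pruned* (default: 8-connected components below 5
  px). Noise survivors of thresholding are isolated specks; genuine edges
  form ridges. On the default noisy phantom pair this step takes the
  Roberts map from ~15% to ~95-100% edge purity against the analytic
  boundary.
* *The outermost 1-px frame is excluded*: gradients there are one-sided
  and profile lines would leave the image.
* Canny's hysteresis uses `low = 0.4 * high` when only one threshold is
  given, with Gaussian presmoothing sigma = 1 px by default.

**Steepness.** For each edge pixel, the maximum gradient magnitude over a
3x3 neighborhood (window clipped at borders). The window absorbs the
1-pixel uncertainty of edge localization. Units: normalized intensity per
pixel.

**Width.** An intensity profile is sampled through each edge pixel along
the local gradient direction (the edge-spread-function construction),
half-length 5 px at 0.25-px spacing. The 10--90% width is the distance
between the upward crossings of `min + 0.1*contrast` and
`min + 0.9*contrast` nearest the profile center, with sub-sample linear
interpolation. Profiles with full contrast below 0.05 (normalized units)
or missing crossings are excluded and counted in `n_valid_widths` — the
10/90 levels of a near-flat profile would measure noise, not an edge.

Profile samples use Catmull-Rom bicubic interpolation by default. This is
a deliberate deviation from plain bilinear sampling: the piecewise-linear
chords of bilinear interpolation systematically dilate the 10--90 rise of
transitions near one pixel wide (by 5--8% at sigma = 1--1.5 px, worst when
the edge falls midway between pixel centers), while the cubic follows the
curvature of the underlying edge-spread function. Calibrated on analytic
erf edges `I(x) = pnorm(x / sigma)` — whose true 10--90 rise is
`2.5631 * sigma` — the bicubic estimator is within 3% for sigma in [1, 3]
at any edge orientation; `interp = "bilinear"` remains available. Note the
absolute widths reported on real images still depend on this convention;
they are calibrated against the erf closed form, not against any specific
prior report's counting convention.

**Contrast.** `max - min` of the image intensities in a window around each
edge pixel. The default window is 11x11, radius equal to the profile
half-length. A 5x5 window was considered and rejected: it sees only ~79%
of the transition of a sigma = 1.6 px edge versus ~93% for sigma = 0.9 px,
so between two images of the *same* scene, the blurrier one measures
artificially lower contrast and the comparison inverts. With radius 5 the
window spans the full transition for sigma up to ~2 px and the measure
reflects tissue contrast across the boundary. The window remains a
parameter (`contrast_win`) and is logged in every result.

## No-reference metrics

**Perceptual blur metric** (re-blur construction): the image is smoothed
with a strong length-9 box filter, horizontally and vertically; the
normalized loss of absolute neighbor differences gives a 0 (sharp) to 1
(blurred) score, taking the worse of the two directions. A known property
of this construction is that *white noise reads as sharpness*: noise
contributes heavily to neighbor differences and vanishes under re-blur, so
a noisy-but-blurry image can score "sharper" than a denoised sharper one.
On the synthetic cohort below this is exactly what happens, and it is the
reason the metric's CR/DLR direction on noisy synthetic pairs opposes what
it shows on real MRI, where structured anatomy dominates the difference
terms. The implementation is kept faithful; the caveat is inherent to the
metric.

**Perceptual sharpness index (PSI)**: block-based statistics of local edge
widths. Widths are measured as above on a thinned Sobel map, converted to
local sharpness `s = w_jnb / width` relative to a just-noticeable-blur
width (default 3 px; `s = 1` marks the perceptibility threshold, `s > 1`
edges sharper than the eye distinguishes), pooled per 32-px block by the
*median*, and PSI is the mean of the top 22% of block values. Two choices
are deliberate:

* The spec of this family of metrics is sometimes phrased as clamping
  widths below `w_jnb` ("maximally sharp"). A hard clamp ties all images
  whose edges are below the threshold — a sigma = 0.5 and a sigma = 1
  phantom would be indistinguishable — destroying the metric's defining
  property of decreasing continuously as sharpness declines. The unclamped
  reciprocal keeps that property; `w_jnb` remains the scale reference.
* Median (not maximum) pooling within blocks: a handful of noise-corrupted
  profiles otherwise masquerades as the sharpest structure in the image
  and inverts comparisons on noisy inputs.

**Blur percentage** (reference metric): `100 * max(0, 1 - HF(test) /
HF(ref))` with `HF` the mean central-difference gradient magnitude. The
construction provably hits both published anchor points: 0% for an
identical pair and 100% for a completely blurred (constant) comparison.

## Reference metrics

SSIM uses the standard Gaussian window (11x11, sigma 1.5, k1 = 0.01,
k2 = 0.03, dynamic range 1); the local map is computed with reflect
padding and the half-window border is cropped before averaging. The
implementation agrees with scikit-image's Gaussian-weighted
`structural_similarity` to 1e-10 on seeded fixtures (frozen in the test
suite). MS-SSIM uses the standard 5-scale weights with 2x2 mean-pool
downsampling; images too small for five scales use fewer with renormalized
weights and a warning. PSNR/SNR report `Inf` for identical pairs,
serialized as the string `"inf"` in CSV output.

## The synthetic phantom cohort

`generate_phantom()` renders an orbital-MRI-like slice — elliptical globe
(intensity 0.55), inner lens (0.85) and a rotated optic-nerve band (0.70)
on a 0.05 background — then applies Gaussian edge blur, seeded additive
Gaussian noise, and clips to [0, 1]. The analytic boundary geometry is
returned with the image, so detector accuracy is testable against ground
truth.

`generate_paired_study()` builds matched cohorts with identical per-subject
geometry (jittered ellipse centers and axes) under two degradation arms:

| arm | edge_sigma (px) | noise_sd | contrast_scale |
|-----|-----------------|----------|----------------|
| CR-like | 1.6 | 0.030 | 1.00 |
| DLR-like | 0.9 | 0.012 | 0.95 |

These defaults *are* the study conditions: the DLR-like arm has narrower
edges, less noise and slightly reduced contrast, so a correct pipeline must
recover steepness up, width down, contrast down for DLR, with a paired
p < 0.001 for steepness at n = 25 (the default cohort size). The reduced
`contrast_scale` deliberately encodes the contrast-reduction direction.

What the phantoms do **not** emulate: Rician magnitude-noise statistics,
k-space undersampling artifacts, coil shading, partial-volume texture, or
any learned-reconstruction nonlinearity. Passing the cohort tests shows the
*measurement chain* recovers known degradation differences; it does not
validate claims about any particular reconstruction algorithm on patient
data.

Two cohort-level directions do **not** reproduce under these conditions,
and are left as documented failures rather than worked around:

* the perceptual blur metric favors the *noisier* CR-like arm (the noise
  confound above; observed ~0.17 CR vs ~0.21 DLR), opposite to its
  direction on real MRI;
* the Roberts-selected contrast difference is marginal (~+-0.01) with a
  seed-dependent sign — per-arm automatic thresholds select different edge
  populations for the noise-sensitive 2x2 kernels. Sobel- and
  Canny-selected contrast reproduce the expected direction robustly.

## Statistics layer

Paired comparisons use the Wilcoxon signed-rank test (zeros dropped; exact
distribution up to 25 tie-free nonzero differences, normal approximation
with tie correction beyond) and the paired t-test, both wrapping the base R
implementations with explicit degenerate-input conventions (all-zero
differences give p = 1; zero-variance nonzero differences give the
infinite-t sentinel). Rater agreement: unweighted Cohen's kappa and
Kendall's tau-b/c by definitional pair counting. Method variability:
within-participant CV (per-subject SD/mean, averaged over subjects — the
per-subject-then-average convention, since pooling order is ambiguous in
the usual verbal definition) and the four two-way mixed ICC forms computed
from the ANOVA mean squares (single/average x consistency/agreement,
verified against an independent `aov`-based oracle to 1e-8). Confidence
intervals for ICC are intentionally omitted; point estimates are what the
report layout carries. Likert data are integers 1--5; no interpolated
medians are produced.

## Problem sizes and determinism

Default problem sizes are chosen so a full validation runs on a laptop
core: 256x256 phantoms, 25-subject cohorts, 100 random 32x32 images for
the exhaustive steepness oracle, erf calibration at four sigmas. The
end-to-end cohort analysis (25 pairs x 3 detectors x both arms, all
metrics) takes about a minute. Everything is deterministic given a seed:
phantom noise is generated under a locally restored RNG state, and a rerun
of `run_study()` on the same manifest produces byte-identical CSVs.

## Known limitations

* Widths depend on the interpolation convention (documented above); only
  relative comparisons across arms are convention-free.
* Steepness from discrete gradients carries a grid-phase dependence of a
  few percent for axis-aligned edges near one-pixel width; rotation
  robustness holds at generic phases.
* The DICOM reader covers explicit-VR little-endian single-frame
  monochrome files (with rescale slope/intercept) and rejects everything
  else loudly; it is a fixture-grade reader, not a PACS client.
* FSIM and WASH are not implemented; `register_metric()` lets users plug
  in external reference or no-reference metrics so report schemas stay
  complete.
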