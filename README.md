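# orbitsharp

Quantitative edge-sharpness and image-quality analysis for paired
comparisons of 2D grayscale medical images — built for the question
"did the accelerated deep-learning reconstruction (DLR) actually produce
sharper boundaries than the conventional reconstruction (CR), and by how
much?"

Radiologists consistently *rate* DLR images as sharper, but Likert scores
cannot localize what changed. orbitsharp measures the boundary itself. For
an image $I$ with central-difference gradient $G = (G_x, G_y)$ and an edge
map from Roberts, Sobel or Canny detection, it computes per edge pixel:

* **edge steepness** — $\max \sqrt{G_x^2 + G_y^2}$ over a small (3×3)
  neighborhood of the edge pixel: the rate of intensity change across the
  boundary, rotationally invariant through the Euclidean gradient norm;
* **edge width** — the distance over which intensity rises from 10% to
  90% of its full contrast along an intensity profile line taken through
  the edge pixel in the gradient direction (the edge-spread-function
  construction; for a Gaussian-blurred step of SD $\sigma$ the true value
  is $2.5631\,\sigma$, which the estimator reproduces within 3%);
* **edge contrast** — max − min intensity in a local (11×11) neighborhood
  of the edge pixel.

Around this core: reference metrics (SSIM, MS-SSIM, SNR, PSNR, blur
percentage), no-reference metrics (perceptual blur metric, perceptual
sharpness index), a synthetic orbital-phantom generator with analytically
known edges for validation, the statistics layer of a paired reading study
(Wilcoxon signed-rank, paired t, Cohen's κ, Kendall's τ-b/c,
within-participant CV, two-way mixed ICC in all four forms), and a batch
pipeline that turns a CSV manifest of image pairs into report-style
tables.

## Worked example

Generate a matched CR-like / DLR-like phantom pair (same anatomy, the
CR-like arm blurrier and noisier) and measure both:

```r
library(orbitsharp)

cr  <- generate_phantom(phantom_spec(edge_sigma = 1.6, noise_sd = 0.030, seed = 42))
dlr <- generate_phantom(phantom_spec(edge_sigma = 0.9, noise_sd = 0.012,
                                     contrast_scale = 0.95, seed = 43))

summarize_edge_features(cr,  "sobel")
#> <edge_feature_result> sobel
#>   steepness 0.1450  width 4.762 px (788/788 valid)  contrast 0.6078
summarize_edge_features(dlr, "sobel")
#> <edge_feature_result> sobel
#>   steepness 0.1836  width 2.577 px (808/808 valid)  contrast 0.5202

ssim(cr, dlr)
#> [1] 0.5262615
psi(cr)$value; psi(dlr)$value
#> [1] 0.6906657
#> [1] 1.223156
```

Reading: the DLR-like image has steeper edges (0.18 vs 0.15 intensity/px),
edges roughly half as wide (2.6 vs 4.8 px — the CR arm's σ = 1.6 blur
spreads each transition further), slightly lower edge contrast (its shape
intensities were scaled by 0.95), and a higher perceptual sharpness index.
The low SSIM between the two arms reflects their very different noise
levels, not structural change.

A whole cohort goes through the same chain in one call:

```r
coh <- generate_paired_study(n_subjects = 25, seed = 11, write_dir = "cohort")
rep <- run_study("cohort/manifest.csv", out_dir = "report")
rep$paired_tests   # per-metric CR vs DLR Wilcoxon + paired-t table
```

`run_study()` writes `pairs.csv` (one row per image pair),
`summary.csv` (per-sequence mean ± SD), `paired_tests.csv`,
`detector_agreement.csv` (within-participant CV and two-way mixed ICC of
each feature across Roberts/Sobel/Canny) and a `run_log.json` with every
parameter — a rerun on the same manifest is byte-identical.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/orbitsharp.R phantom  --out dir/ --n 25 --seed 7
Rscript inst/cli/orbitsharp.R features --image img.tif --detector canny
Rscript inst/cli/orbitsharp.R metrics  --ref a.tif --test b.tif
Rscript inst/cli/orbitsharp.R study    --manifest manifest.csv --out report/
```

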