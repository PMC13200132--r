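Package: orbitsharp
Title: Quantitative Edge-Sharpness and Image-Quality Analysis for Paired MRI Reconstructions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies edge sharpness and image quality in 2D grayscale
    medical images, built for paired comparisons of conventionally
    reconstructed versus deep-learning reconstructed MRI. Implements edge
    extraction (Roberts, Sobel, Canny), per-edge-pixel feature extraction
    (edge steepness from the local central-difference gradient magnitude,
    10-90 percent edge width from interpolated intensity profiles, local
    edge contrast), reference similarity metrics (SSIM, MS-SSIM, SNR, PSNR,
    blur percentage), no-reference sharpness metrics (perceptual blur
    metric, perceptual sharpness index), the agreement statistics used to
    summarize them (Wilcoxon signed-rank, paired t, Cohen's kappa,
    Kendall's tau-b/c, within-participant CV, two-way mixed ICC), and a
    synthetic orbital phantom generator with analytically known edges for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    RNifti,
    EBImage,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
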