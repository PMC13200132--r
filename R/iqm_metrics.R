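#' Structural similarity index (SSIM)
#'
#' Mean local SSIM between two equally sized normalized images, computed
#' with a Gaussian weighting window (default 11 x 11, sigma 1.5) and the
#' usual stabilizers `C1 = (k1 L)^2`, `C2 = (k2 L)^2` with dynamic range
#' `L = 1` on the normalized scale. The local map is computed with
#' reflect-padded Gaussian filtering and the outermost half-window border is
#' cropped before averaging, so values agree with the common
#' Gaussian-weighted reference implementations.
#'
#' @param ref,test normalized [gray_image]s of equal dimensions.
#' @param sigma Gaussian window SD in px (default 1.5).
#' @param win_size window side (odd, default 11).
#' @param k1,k2 stabilizer constants (defaults 0.01, 0.03).
#' @param data_range dynamic range `L` (default 1).
#' @return SSIM value in \[-1, 1\].
#' @export
ssim <- function(ref, test, sigma = 1.5, win_size = 11L, k1 = 0.01,
                 k2 = 0.03, data_range = 1) {
  s <- ssim_components(ref, test, sigma, win_size, k1, k2, data_range)
  mean(s$ssim_map)
}

ssim_components <- function(ref, test, sigma = 1.5, win_size = 11L,
                            k1 = 0.01, k2 = 0.03, data_range = 1) {
  stopifnot_gray(ref, normalized = TRUE); stopifnot_gray(test, normalized = TRUE)
  if (!all(dim(ref) == dim(test)))
    stop("reference and test images must have identical dimensions", call. = FALSE)
  x <- ref$pixels; y <- test$pixels
  r <- (win_size - 1L) %/% 2L
  k <- gaussian_kernel_1d(sigma, radius = r)
  f <- function(m) filter_sep(m, k, mode = "reflect")
  mx <- f(x); my <- f(y)
  vx <- f(x * x) - mx^2
  vy <- f(y * y) - my^2
  cxy <- f(x * y) - mx * my
  c1 <- (k1 * data_range)^2; c2 <- (k2 * data_range)^2
  lum <- (2 * mx * my + c1) / (mx^2 + my^2 + c1)
  cs <- (2 * cxy + c2) / (vx + vy + c2)
  crop <- function(m) {
    if (nrow(m) > 2 * r && ncol(m) > 2 * r)
      m[(r + 1L):(nrow(m) - r), (r + 1L):(ncol(m) - r), drop = FALSE]
    else m
  }
  list(ssim_map = crop(lum * cs), cs_map = crop(cs))
}

#' Multi-scale SSIM (MS-SSIM)
#'
#' Weighted product of contrast-structure terms over dyadic scales with the
#' luminance term at the coarsest scale, using the standard 5-scale weights
#' (0.0448, 0.2856, 0.3001, 0.2363, 0.1333). Images too small for 5 scales
#' (each scale needs both sides > 2x the window radius after halving) use
#' fewer scales with renormalized weights; a warning reports the reduction.
#'
#' @inheritParams ssim
#' @param weights per-scale exponents; truncated and renormalized as needed.
#' @return MS-SSIM value.
#' @export
ms_ssim <- function(ref, test, weights = c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333),
                    sigma = 1.5, win_size = 11L, k1 = 0.01, k2 = 0.03,
                    data_range = 1) {
  stopifnot_gray(ref, normalized = TRUE); stopifnot_gray(test, normalized = TRUE)
  if (!all(dim(ref) == dim(test)))
    stop("reference and test images must have identical dimensions", call. = FALSE)
  min_side <- min(dim(ref))
  # each scale halves the image; require side >= win_size at the last scale
  max_scales <- max(1L, 1L + floor(log2(min_side / win_size)))
  n_scales <- min(length(weights), max_scales)
  if (n_scales < length(weights)) {
    warning(sprintf("image too small for %d scales; using %d with renormalized weights",
                    length(weights), n_scales), call. = FALSE)
    weights <- weights[seq_len(n_scales)] / sum(weights[seq_len(n_scales)])
  }
  x <- ref; y <- test
  vals <- numeric(n_scales)
  for (s in seq_len(n_scales)) {
    comp <- ssim_components(x, y, sigma, win_size, k1, k2, data_range)
    vals[s] <- if (s == n_scales) mean(comp$ssim_map) else mean(comp$cs_map)
    if (s < n_scales) { x <- downsample2(x); y <- downsample2(y) }
  }
  prod(sign(vals) * abs(vals)^weights)
}

downsample2 <- function(img) {
  m <- img$pixels
  H <- 2L * (nrow(m) %/% 2L); W <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(H), seq_len(W), drop = FALSE]
  out <- (m[seq(1, H, 2), seq(1, W, 2)] + m[seq(2, H, 2), seq(1, W, 2)] +
          m[seq(1, H, 2), seq(2, W, 2)] + m[seq(2, H, 2), seq(2, W, 2)]) / 4
  g <- gray_image(out, source_id = img$source_id)
  g$normalized <- TRUE   # 2x2 averaging cannot leave [0, 1]
  g
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(peak^2 / MSE)` in dB. Identical images have zero MSE
#' and return `Inf`.
#'
#' @param ref,test normalized [gray_image]s of equal dimensions.
#' @param peak dynamic-range peak (default 1 on the normalized scale).
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(ref, test, peak = 1) {
  check_pair(ref, test)
  mse <- mean((ref$pixels - test$pixels)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Signal-to-noise ratio of a test image against a reference
#'
#' `SNR = 10 log10(sum(ref^2) / sum((ref - test)^2))` in dB; identical
#' images return `Inf`.
#'
#' @inheritParams psnr
#' @return SNR in dB.
#' @export
snr_ref <- function(ref, test) {
  check_pair(ref, test)
  noise <- sum((ref$pixels - test$pixels)^2)
  if (noise == 0) return(Inf)
  10 * log10(sum(ref$pixels^2) / noise)
}

check_pair <- function(ref, test) {
  stopifnot_gray(ref, normalized = TRUE); stopifnot_gray(test, normalized = TRUE)
  if (!all(dim(ref) == dim(test)))
    stop("reference and test images must have identical dimensions", call. = FALSE)
}

#' Reference blur percentage
#'
#' Percentage of high-frequency content of the reference lost in the test
#' image: `100 * max(0, 1 - HF(test) / HF(ref))`, where `HF` is the mean
#' central-difference gradient magnitude, clamped to \[0, 100\]. An
#' identical pair scores 0% and a completely blurred (constant) test image
#' scores 100%. A contentless reference (`HF = 0`) returns 0 with a warning.
#'
#' @inheritParams psnr
#' @return Blur percentage in \[0, 100\].
#' @export
blur_percentage <- function(ref, test) {
  check_pair(ref, test)
  hf <- function(img) mean(compute_gradient(img)$magnitude)
  h0 <- hf(ref)
  if (h0 == 0) {
    warning("reference has no gradient content; blur percentage undefined, returning 0",
            call. = FALSE)
    return(0)
  }
  min(100, max(0, 100 * (1 - hf(test) / h0)))
}

#' No-reference perceptual blur metric
#'
#' Quantifies pre-existing blur by re-blurring: the image is smoothed with a
#' strong length-9 box filter, horizontally and vertically; the total
#' absolute neighbor-difference (horizontal and vertical separately) is
#' compared before and after. A sharp image loses much neighbor variation
#' when re-blurred (score near 0); an already-blurred image loses little
#' (score near 1). The final value is the worse (larger) of the two
#' directional scores. A constant image returns 1 with a warning.
#'
#' @param img a normalized [gray_image].
#' @param box_len length of the averaging filter (default 9).
#' @return Blur value in \[0, 1\].
#' @export
perceptual_blur_metric <- function(img, box_len = 9L) {
  stopifnot_gray(img, normalized = TRUE, min_side = 8L)
  m <- img$pixels
  k <- rep(1 / box_len, box_len)
  bver <- t(filter_rows(t(m), k))   # vertical blur (along rows/columns)
  bhor <- filter_rows(m, k)         # horizontal blur
  dv <- function(x) abs(x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE])
  dh <- function(x) abs(x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE])
  score <- function(d_f, d_b) {
    s_f <- sum(d_f)
    if (s_f == 0) return(NA_real_)
    s_v <- sum(pmax(0, d_f - d_b))
    (s_f - s_v) / s_f
  }
  b_ver <- score(dv(m), dv(bver))
  b_hor <- score(dh(m), dh(bhor))
  if (is.na(b_ver) && is.na(b_hor)) {
    warning("constant image: perceptual blur metric set to 1", call. = FALSE)
    return(1)
  }
  max(b_ver, b_hor, na.rm = TRUE)
}

#' Perceptual sharpness index (PSI)
#'
#' No-reference sharpness score from the statistics of local edge widths.
#' Edges are located with a thinned Sobel map, 10--90% widths are measured
#' on gradient-normal profiles (see [edge_width()]) and converted to a
#' local sharpness `s = w_jnb / width` relative to the just-noticeable-blur
#' width: `s = 1` marks an edge at the perceptibility threshold and `s > 1`
#' an edge sharper than the eye can distinguish. The image is partitioned
#' into blocks; each block's local sharpness is the median over its edges
#' (the median, not the maximum, so a handful of noise-corrupted profiles
#' cannot masquerade as sharp structure), and PSI is the mean of the
#' highest `top_frac` fraction of block sharpness values, so it tracks the
#' sharpest structures present and decreases continuously as edge
#' sharpness declines.
#'
#' @param img a normalized [gray_image].
#' @param block_size block side in px (default 32).
#' @param top_frac fraction of sharpest blocks averaged (default 0.22).
#' @param w_jnb just-noticeable-blur width in px (default 3).
#' @param detector_params parameters for the Sobel edge map.
#' @param half_length,spacing,contrast_floor profile parameters.
#' @return List: `value` (PSI >= 0), `n_blocks`, `n_edges`, `valid`
#'   (FALSE when the image has no usable edges).
#' @export
psi <- function(img, block_size = 32L, top_frac = 0.22, w_jnb = 3,
                detector_params = list(), half_length = 5, spacing = 0.25,
                contrast_floor = 0.05) {
  stopifnot_gray(img, normalized = TRUE, min_side = 8L)
  edges <- detect_edges(img, "sobel", detector_params)
  invalid <- list(value = NA_real_, n_blocks = 0L, n_edges = 0L, valid = FALSE)
  if (edges$n_edge_pixels == 0L) return(invalid)
  grad <- compute_gradient(img)
  widths <- profile_widths(img, edges$mask, grad, half_length, spacing,
                           contrast_floor)  # default bicubic sampling
  px <- which(edges$mask, arr.ind = TRUE)
  keep <- !is.na(widths)
  if (!any(keep)) return(invalid)
  sharp <- w_jnb / pmax(widths[keep], spacing)
  blk <- (px[keep, 1] - 1L) %/% block_size * 10000L + (px[keep, 2] - 1L) %/% block_size
  block_sharp <- tapply(sharp, blk, stats::median)
  ntop <- max(1L, ceiling(top_frac * length(block_sharp)))
  list(value = mean(sort(block_sharp, decreasing = TRUE)[seq_len(ntop)]),
       n_blocks = length(block_sharp), n_edges = sum(keep), valid = TRUE)
}

# --- pluggable metric registry ------------------------------------------

.metric_registry <- new.env(parent = emptyenv())

#' Register or list external image-quality metrics
#'
#' Third-party full-reference metrics (e.g. published feature- or
#' wavelet-based similarity indices) can be plugged in by name so pipeline
#' reports keep a complete schema: a reference metric is a
#' `function(ref, test)` and a no-reference metric a `function(img)`, each
#' returning a single number.
#'
#' @param name metric name used in reports.
#' @param fn the metric callable.
#' @param reference logical; TRUE for full-reference metrics.
#' @return `register_metric` returns `name` invisibly; `list_metrics`
#'   returns a data.frame of registered metrics.
#' @export
register_metric <- function(name, fn, reference = TRUE) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, list(fn = fn, reference = isTRUE(reference)), envir = .metric_registry)
  invisible(name)
}

#' @rdname register_metric
#' @export
list_metrics <- function() {
  nm <- ls(.metric_registry)
  data.frame(name = nm,
             reference = vapply(nm, function(n) get(n, .metric_registry)$reference,
                                logical(1)),
             row.names = NULL)
}

get_registered_metric <- function(name) {
  if (!exists(name, envir = .metric_registry, inherits = FALSE))
    stop("no registered metric named '", name, "'", call. = FALSE)
  get(name, envir = .metric_registry)
}
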