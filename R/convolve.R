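# Small separable-filter utilities shared by the Canny detector, the
# Gaussian-windowed SSIM and the phantom generator. Padding is by edge
# replication ("replicate") or mirroring ("reflect", scipy-style half-sample
# symmetry) so that flat regions stay flat under smoothing.

pad_matrix <- function(m, r, mode = c("replicate", "reflect")) {
  mode <- match.arg(mode)
  if (r == 0L) return(m)
  n <- nrow(m); p <- ncol(m)
  idx <- function(k, size) {
    i <- seq.int(1L - r, size + r)
    if (mode == "replicate") pmin(pmax(i, 1L), size)
    else {                      # reflect: ... 2 1 | 1 2 ... n | n n-1 ...
      i <- ifelse(i < 1L, 1L - i, i)
      ifelse(i > size, 2L * size + 1L - i, i)
    }
  }
  m[idx(r, n), , drop = FALSE][, idx(r, p), drop = FALSE]
}

# Correlate each row with a centered odd-length kernel.
filter_rows <- function(m, kernel, mode = "replicate") {
  k <- length(kernel)
  stopifnot(k %% 2L == 1L)
  r <- (k - 1L) %/% 2L
  mp <- pad_matrix(m, r, mode)[(r + 1L):(r + nrow(m)), , drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_len(k))
    out <- out + kernel[j] * mp[, j:(j + ncol(m) - 1L), drop = FALSE]
  out
}

filter_sep <- function(m, kernel, mode = "replicate")
  t(filter_rows(t(filter_rows(m, kernel, mode)), kernel, mode))

gaussian_kernel_1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- seq.int(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_blur <- function(m, sigma, mode = "replicate", radius = NULL) {
  if (sigma <= 0) return(m)
  k <- if (is.null(radius)) gaussian_kernel_1d(sigma)
       else gaussian_kernel_1d(sigma, radius)
  filter_sep(m, k, mode)
}

# Full 2D correlation with a small kernel (used for Roberts/Sobel).
filter_2d <- function(m, kernel, mode = "replicate") {
  kr <- nrow(kernel); kc <- ncol(kernel)
  r <- max(kr, kc) %/% 2L
  mp <- pad_matrix(m, r, mode)
  out <- matrix(0, nrow(m), ncol(m))
  # top-left of the kernel sits at offset (a, b) from the output pixel
  a0 <- r - (kr - 1L) %/% 2L
  b0 <- r - (kc - 1L) %/% 2L
  for (i in seq_len(kr)) for (j in seq_len(kc)) {
    if (kernel[i, j] == 0) next
    out <- out + kernel[i, j] *
      mp[(a0 + i):(a0 + i + nrow(m) - 1L), (b0 + j):(b0 + j + ncol(m) - 1L), drop = FALSE]
  }
  out
}

shift_matrix <- function(m, dr, dc, fill = 0) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  rs <- max(1L, 1L + dr):min(n, n + dr)
  cs <- max(1L, 1L + dc):min(p, p + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}
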