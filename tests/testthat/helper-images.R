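# Fixture builders shared across the suite. All images are constructed in
# code; nothing binary is read from disk except files the tests write first.

norm_img <- function(m, id = "") {
  g <- gray_image(m, source_id = id)
  g$normalized <- TRUE
  g
}

# vertical unit step: 0 in columns 1..split, 1 after
step_image <- function(h = 32, w = 32, split = w %/% 2) {
  norm_img(cbind(matrix(0, h, split), matrix(1, h, w - split)))
}

# horizontal linear ramp 0..1 left to right
ramp_image <- function(h = 16, w = 16) {
  norm_img(matrix(rep((seq_len(w) - 1) / (w - 1), each = h), h, w))
}

# Gaussian-blurred step (analytic erf edge) at angle theta, edge through center
erf_image <- function(sigma, theta = 0, n = 96) {
  ctr <- (n + 1) / 2
  d <- outer(seq_len(n), seq_len(n),
             function(r, c) (c - ctr) * cos(theta) + (r - ctr) * sin(theta))
  norm_img(pnorm(d / sigma))
}

# hard or blurred disk of given radius on a dark background
disk_image <- function(radius = 30, n = 128, lo = 0, hi = 1, sigma = 0) {
  ctr <- (n + 1) / 2
  dist <- outer(seq_len(n), seq_len(n),
                function(r, c) sqrt((r - ctr)^2 + (c - ctr)^2))
  m <- ifelse(dist <= radius, hi, lo)
  if (sigma > 0) m <- orbitsharp:::gaussian_blur(m, sigma)
  norm_img(m)
}

disk_center <- function(n = 128) (n + 1) / 2

checkerboard_image <- function(n = 64) {
  norm_img(matrix(outer(seq_len(n), seq_len(n), `+`) %% 2, n, n))
}

# edge map wrapper for hand-made masks
manual_edge_map <- function(mask, detector = "sobel") {
  structure(list(mask = mask, detector = detector, threshold_used = NA_real_,
                 n_edge_pixels = sum(mask)),
            class = "edge_map")
}
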