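#' Edge detection with Roberts, Sobel or Canny
#'
#' Produces a binary edge map used downstream only to select the pixels at
#' which edge features are measured. Roberts applies the 2 x 2 diagonal
#' kernels and Sobel the standard 3 x 3 kernels; both threshold the
#' detector's gradient magnitude (Otsu by default, see [auto_threshold()])
#' and by default thin the result to ~1-px ridges by non-maximum suppression
#' along the gradient. Canny runs Gaussian presmoothing, Sobel gradients,
#' non-maximum suppression and hysteresis with `(low, high)` thresholds.
#' The outermost 1-px frame is always excluded: gradients there are
#' one-sided and profile lines would leave the image.
#'
#' @param img a normalized [gray_image].
#' @param detector `"roberts"`, `"sobel"` or `"canny"`.
#' @param params named list of overrides: `threshold` (Roberts/Sobel),
#'   `thin` (logical, default `TRUE`), `sigma` (Canny presmoothing SD in px,
#'   default 1.0), `low`, `high` (Canny hysteresis; default from
#'   [auto_threshold()] with `low = 0.4 * high`), `min_component`
#'   (default 5: connected edge components smaller than this many pixels
#'   are discarded — isolated noise responses rarely form ridges).
#'   Automatic thresholds are computed from the thinned (non-maximum
#'   suppressed) magnitudes when thinning is active, so the split is not
#'   swamped by off-ridge pixels.
#' @return An object of class `edge_map`: `mask` (logical H x W),
#'   `detector`, `threshold_used`, `n_edge_pixels`.
#' @export
detect_edges <- function(img, detector = c("sobel", "roberts", "canny"),
                         params = list()) {
  stopifnot_gray(img, normalized = TRUE, min_side = 8L)
  detector <- match.arg(detector)
  m <- img$pixels

  if (detector == "canny") {
    sigma <- params$sigma %||% 1.0
    sm <- gaussian_blur(m, sigma)
    gx <- filter_2d(sm, .sobel_x); gy <- filter_2d(sm, .sobel_y)
    mag <- zero_floor(sqrt(gx^2 + gy^2))
    thin <- nonmax_suppress(mag, gx, gy)
    if (is.null(params$high)) {
      thr <- auto_threshold(mag * thin, policy = "canny")
      low <- params$low %||% thr[1]; high <- thr[2]
    } else {
      high <- params$high; low <- params$low %||% (0.4 * high)
    }
    if (low >= high && high > 0)
      stop("Canny thresholds require low < high", call. = FALSE)
    mask <- hysteresis(mag * thin, low, high)
    thr_used <- c(low = low, high = high)
  } else {
    if (detector == "roberts") {
      g1 <- filter_2d(m, matrix(c(1, 0, 0, -1), 2, 2))
      g2 <- filter_2d(m, matrix(c(0, 1, -1, 0), 2, 2))
      # rotate diagonal responses back to axis-aligned components for NMS
      gx <- (g1 - g2) / sqrt(2); gy <- (g1 + g2) / sqrt(2)
    } else {
      gx <- filter_2d(m, .sobel_x); gy <- filter_2d(m, .sobel_y)
    }
    mag <- zero_floor(sqrt(gx^2 + gy^2))
    do_thin <- params$thin %||% TRUE
    thin <- if (do_thin) nonmax_suppress(mag, gx, gy)
            else matrix(TRUE, nrow(mag), ncol(mag))
    thr_used <- params$threshold %||%
      auto_threshold(if (do_thin) mag * thin else mag, policy = "otsu")
    mask <- mag > thr_used & thin
  }
  mask <- prune_small_components(mask, params$min_component %||% 5L)

  mask[c(1L, nrow(mask)), ] <- FALSE
  mask[, c(1L, ncol(mask))] <- FALSE
  structure(list(mask = mask, detector = detector, threshold_used = thr_used,
                 n_edge_pixels = sum(mask)),
            class = "edge_map")
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("<edge_map> %s: %d edge pixels on %d x %d (threshold %s)\n",
              x$detector, x$n_edge_pixels, nrow(x$mask), ncol(x$mask),
              paste(signif(x$threshold_used, 4), collapse = "/")))
  invisible(x)
}

.sobel_x <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) / 8
.sobel_y <- t(.sobel_x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Filtering a flat field leaves O(1e-17) arithmetic residue; clamp it so
# "zero gradient" means zero downstream (empty maps on constant images).
zero_floor <- function(mag, eps = 1e-12) { mag[mag < eps] <- 0; mag }

#' Automatic gradient-magnitude threshold
#'
#' Otsu's split of the nonzero gradient magnitudes (256-bin histogram). The
#' `"canny"` policy returns the pair `(0.4 * t, t)` with `t` the Otsu value,
#' used as hysteresis thresholds. An all-zero magnitude field yields 0 and
#' the caller emits an empty edge map. A near-uniform distribution (relative
#' spread below 20% of the maximum) is a single class — every candidate is
#' an edge — so it is not split: the threshold falls just below the minimum.
#'
#' @param magnitude non-negative matrix of gradient magnitudes.
#' @param policy `"otsu"` or `"canny"`.
#' @return A single threshold, or `c(low, high)` for `"canny"`.
#' @export
auto_threshold <- function(magnitude, policy = c("otsu", "canny")) {
  policy <- match.arg(policy)
  stopifnot(all(magnitude >= 0))
  v <- magnitude[magnitude > 0]
  t <- if (length(v) < 2L || min(v) == max(v)) 0
       else if (max(v) - min(v) < 0.2 * max(v)) 0.999 * min(v)
       else otsu_split(v)
  if (policy == "canny") c(low = 0.4 * t, high = t) else t
}

# Otsu on a 256-bin histogram of the values; returns the bin-edge threshold
# maximizing between-class variance.
otsu_split <- function(v, nbins = 256L) {
  lo <- min(v); hi <- max(v)
  h <- tabulate(pmin(as.integer((v - lo) / (hi - lo) * nbins) + 1L, nbins), nbins)
  p <- h / sum(h)
  mids <- lo + (seq_len(nbins) - 0.5) * (hi - lo) / nbins
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- (mu_t * w0 - mu)^2 / (w0 * w1)
  bcv[!valid] <- -Inf
  k <- which.max(bcv)
  lo + k * (hi - lo) / nbins
}

# Keep pixels that are local maxima of `mag` along the quantized gradient
# direction (4 orientations). Returns a logical matrix.
nonmax_suppress <- function(mag, gx, gy) {
  ang <- atan2(gy, gx)                 # [-pi, pi]
  ang <- ang %% pi                     # orientation, [0, pi)
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  # sector 0: horizontal gradient -> compare left/right (columns)
  # 1: diagonal dr=+1, dc=+1 ; 2: vertical -> up/down (rows); 3: dr=+1, dc=-1
  off <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  for (s in 0:3) {
    d <- off[[s + 1L]]
    n1 <- shift_matrix(mag, d[1], d[2], fill = 0)
    n2 <- shift_matrix(mag, -d[1], -d[2], fill = 0)
    sel <- sector == s & mag >= n1 & mag >= n2 & mag > 0
    keep <- keep | sel
  }
  keep
}

# 8-connected component labels of a logical mask. bwlabel is 4-connected,
# so labels touching diagonally are merged with a union-find pass.
label8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (d in list(c(1L, 1L), c(1L, -1L))) {
    sh <- shift_matrix(lab, d[1], d[2], fill = 0)
    sel <- lab > 0 & sh > 0 & lab != sh
    if (!any(sel)) next
    pairs <- unique(cbind(lab[sel], sh[sel]))
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[b] <- a
    }
  }
  root <- vapply(seq_len(nlab), find, numeric(1))
  lab[lab > 0] <- root[lab[lab > 0]]
  lab
}

# Hysteresis linking: keep connected components (8-connectivity) of
# above-low pixels that contain at least one above-high pixel.
hysteresis <- function(mag, low, high) {
  weak <- mag > low & mag > 0
  strong <- mag > high
  if (!any(strong)) return(matrix(FALSE, nrow(mag), ncol(mag)))
  lab <- label8(weak)
  keep_ids <- unique(lab[strong])
  keep_ids <- keep_ids[keep_ids > 0]
  matrix(lab %in% keep_ids, nrow(mag), ncol(mag))
}

# Drop 8-connected components smaller than min_size pixels. Isolated
# noise-induced responses rarely form ridges; genuine edges do.
prune_small_components <- function(mask, min_size) {
  if (min_size <= 1L || !any(mask)) return(mask)
  lab <- label8(mask)
  sz <- tabulate(lab[lab > 0])
  mask & matrix(lab > 0 & sz[pmax(lab, 1)] >= min_size, nrow(mask))
}
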